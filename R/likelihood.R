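# Joint ordinal-continuous FIML likelihood.
#
# Each family contributes the marginal likelihood of its observed elements:
# observed continuous values enter through a multivariate-normal density;
# observed binary values enter through the conditional (given the continuous
# values) normal probability of the liability rectangle, (threshold, Inf)
# for affected and (-Inf, threshold] for unaffected. Missing elements are
# marginalized (missing-at-random). Families are independent, so the total
# -2LL is -2 times the sum of family contributions. For speed, families are
# grouped by (zygosity-sex group, missingness pattern) and each block is
# evaluated with vectorized linear algebra; at most a bivariate rectangle is
# ever needed because conditioning on the continuous elements is analytic.

# element order within a pair family: (l1, y1, l2, y2); singletons: (l, y)
.lik_positions <- function(k) {
  if (k == 4) list(l = c(1L, 3L), y = c(2L, 4L)) else list(l = 1L, y = 2L)
}

# Compile a twin_families object into evaluation blocks.
compile_blocks <- function(tf) {
  w <- tf$wide
  blocks <- list()
  is_sgl <- w$group == GROUP_SGL
  # effective group key: pair groups as-is, singletons split by sex
  key_group <- ifelse(is_sgl, paste0("SGL_", w$sex1), w$group)
  pat <- ifelse(is_sgl,
                paste0(!is.na(w$d1), !is.na(w$y1)),
                paste0(!is.na(w$d1), !is.na(w$y1),
                       !is.na(w$d2), !is.na(w$y2)))
  keys <- split(seq_len(nrow(w)), paste(key_group, pat, sep = "|"))
  for (k in names(keys)) {
    idx <- keys[[k]]
    g <- key_group[idx[1]]
    sgl <- startsWith(g, "SGL_")
    kdim <- if (sgl) 2L else 4L
    obs <- if (sgl) {
      c(!is.na(w$d1[idx[1]]), !is.na(w$y1[idx[1]]))
    } else {
      c(!is.na(w$d1[idx[1]]), !is.na(w$y1[idx[1]]),
        !is.na(w$d2[idx[1]]), !is.na(w$y2[idx[1]]))
    }
    if (!any(obs)) next
    blocks[[length(blocks) + 1]] <- list(
      group = if (sgl) GROUP_SGL else g,
      sex = if (sgl) sub("SGL_", "", g) else NULL,
      sexes = if (sgl) sub("SGL_", "", g) else group_sexes(g),
      obs = obs, kdim = kdim, n = length(idx),
      Y = as.matrix(w[idx, c("y1", "y2")[seq_len(kdim / 2)], drop = FALSE]),
      D = as.matrix(w[idx, c("d1", "d2")[seq_len(kdim / 2)], drop = FALSE]),
      AGE = as.matrix(w[idx, c("age1", "age2")[seq_len(kdim / 2)],
                        drop = FALSE])
    )
  }
  blocks
}

# Log-likelihood of one compiled block under params. Returns sum over
# families in the block.
block_loglik <- function(blk, params, underflow_floor = 1e-300,
                         warn_underflow = TRUE) {
  pos <- .lik_positions(blk$kdim)
  if (blk$kdim == 4) {
    S <- expected_pair_covariance(params, blk$group, check = FALSE)
    mu <- c(0, params$mu[[blk$sexes[1]]], 0, params$mu[[blk$sexes[2]]])
  } else {
    S <- within_person_cov(params, blk$sex)
    mu <- c(0, params$mu[[blk$sex]])
  }
  if (any(!is.finite(S))) stop("non-finite implied covariance")
  obs_idx <- which(blk$obs)
  cont <- intersect(obs_idx, pos$y)
  bin <- intersect(obs_idx, pos$l)
  member_of <- function(el) ceiling(el / 2)  # element -> member index
  ll <- numeric(blk$n)
  if (length(cont)) {
    ycols <- match(member_of(cont), seq_len(ncol(blk$Y)))
    Yc <- blk$Y[, ycols, drop = FALSE]
    Scc <- S[cont, cont, drop = FALSE]
    U <- chol(Scc)
    Q <- backsolve(U, t(Yc) - mu[cont], transpose = TRUE)
    ll <- ll - 0.5 * colSums(Q^2) - sum(log(diag(U))) -
      0.5 * length(cont) * log(2 * pi)
  }
  if (length(bin)) {
    mem <- member_of(bin)
    sexes_b <- blk$sexes[mem]
    tau <- t(unname(params$thresholds[sexes_b]) +
               params$beta_age *
               (t(blk$AGE[, mem, drop = FALSE]) - params$age_center))
    D <- blk$D[, mem, drop = FALSE]
    if (length(cont)) {
      Sbc <- S[bin, cont, drop = FALSE]
      B <- Sbc %*% chol2inv(chol(S[cont, cont, drop = FALSE]))
      cm <- t(mu[bin] + B %*% (t(blk$Y[, match(member_of(cont),
                                               seq_len(ncol(blk$Y))),
                                       drop = FALSE]) - mu[cont]))
      cv <- S[bin, bin, drop = FALSE] - B %*% t(Sbc)
    } else {
      cm <- matrix(mu[bin], blk$n, length(bin), byrow = TRUE)
      cv <- S[bin, bin, drop = FALSE]
    }
    sds <- sqrt(diag(cv))
    if (any(!is.finite(sds)) || any(sds <= 0))
      stop("degenerate conditional liability variance")
    if (length(bin) == 1) {
      sg <- 2 * D[, 1] - 1
      ll <- ll + stats::pnorm(sg * (cm[, 1] - tau[, 1]) / sds[1],
                              log.p = TRUE)
    } else {
      rho <- cv[1, 2] / (sds[1] * sds[2])
      p <- bvn_rect_prob(tau[, 1], tau[, 2], D[, 1], D[, 2],
                         cm[, 1], cm[, 2], sds[1], sds[2], rho)
      if (any(p < underflow_floor)) {
        if (warn_underflow)
          warning("rectangle probability underflow; flooring in log space")
        p <- pmax(p, underflow_floor)
      }
      ll <- ll + log(p)
    }
  }
  sum(ll)
}

#' Log-likelihood contribution of a single family
#'
#' Evaluates the joint ordinal-continuous likelihood of one family given its
#' model-implied moments ([implied_moments()]). Elements with missing values
#' are marginalized; thresholds may be infinite (a `-Inf` threshold makes an
#' affected member's binary factor contribute probability 1).
#'
#' @param family A list with numeric vectors `d` (0/1/NA) and `y`
#'   (continuous/NA), one element per member (length 2 for pairs, 1 for
#'   singletons).
#' @param moments A list with `mean`, `cov`, `thresholds` as returned by
#'   [implied_moments()].
#' @return The log-likelihood contribution (log scale).
#' @export
family_loglik <- function(family, moments) {
  k <- length(family$d)
  stopifnot(length(family$y) == k, k %in% c(1L, 2L),
            length(moments$mean) == 2 * k,
            all(dim(moments$cov) == 2 * k),
            length(moments$thresholds) == k)
  if (all(is.na(family$d)) && all(is.na(family$y)))
    stop("family has no observed elements")
  if (any(!is.finite(moments$mean)) || any(!is.finite(moments$cov)))
    stop("non-finite moments")
  pos <- .lik_positions(2 * k)
  obs <- rep(FALSE, 2 * k)
  obs[pos$l[!is.na(family$d)]] <- TRUE
  obs[pos$y[!is.na(family$y)]] <- TRUE
  S <- moments$cov
  mu <- moments$mean
  cont <- intersect(which(obs), pos$y)
  bin <- intersect(which(obs), pos$l)
  ll <- 0
  if (length(cont)) {
    yv <- family$y[match(cont, pos$y)]
    ll <- ll + dmvnorm_log(matrix(yv, 1), mu[cont],
                           S[cont, cont, drop = FALSE])
    B <- S[bin, cont, drop = FALSE] %*%
      solve(S[cont, cont, drop = FALSE])
    cm <- mu[bin] + as.vector(B %*% (yv - mu[cont]))
    cv <- S[bin, bin, drop = FALSE] -
      B %*% t(S[bin, cont, drop = FALSE])
  } else {
    cm <- mu[bin]
    cv <- S[bin, bin, drop = FALSE]
  }
  if (length(bin)) {
    mem <- ceiling(bin / 2)
    tau <- moments$thresholds[mem]
    dv <- family$d[mem]
    sds <- sqrt(diag(cv))
    if (length(bin) == 1) {
      sg <- 2 * dv - 1
      q <- sg * (cm - tau) / sds
      ll <- ll + stats::pnorm(q, log.p = TRUE)
    } else {
      rho <- cv[1, 2] / (sds[1] * sds[2])
      # map infinite thresholds through the sign convention safely
      p <- bvn_rect_prob(tau[1], tau[2], dv[1], dv[2],
                         cm[1], cm[2], sds[1], sds[2], rho)
      p <- max(p, 1e-300)
      ll <- ll + log(p)
    }
  }
  as.numeric(ll)
}

#' Total -2 log-likelihood of a prepared dataset
#'
#' Sums the family log-likelihood contributions over all families (which are
#' independent) and returns minus twice the sum.
#'
#' @param data A `twin_families` object from [pair_assembly()], or a cohort
#'   data.frame (then [prepare_cohort()] is applied).
#' @param params An `ace_params` parameter set.
#' @return The -2LL (scalar).
#' @export
total_minus2ll <- function(data, params) {
  if (!inherits(data, "twin_families")) data <- prepare_cohort(data)
  if (nrow(data$wide) == 0) stop("no families in data")
  blocks <- attr(data, "blocks") %||% compile_blocks(data)
  -2 * sum(vapply(blocks, block_loglik, numeric(1), params = params))
}
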