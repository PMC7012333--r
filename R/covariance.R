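# Model-implied moments for twin families.

#' Model-implied latent covariance of a twin pair
#'
#' Returns the 4x4 covariance matrix of the latent vector
#' (liability1, continuous1, liability2, continuous2) implied by a parameter
#' set for one zygosity-sex group. Within-person blocks are
#' `a a' + c c' + e e'` for the member's sex; the cross-twin block is
#' `A + C` for MZ pairs, `0.5 A + C` for same-sex DZ pairs, and
#' `a_M G a_F' + c_M H c_F'` for opposite-sex pairs (member 1 male).
#' E is never shared between twins.
#'
#' @param params An `ace_params`/[sim_params()] parameter set.
#' @param group One of `"MZM"`, `"MZF"`, `"DZM"`, `"DZF"`, `"DZOS"`.
#' @param check If `TRUE` (default), validate parameters and verify the
#'   result is positive semi-definite.
#' @return A symmetric 4x4 matrix with dimnames
#'   `c("l1", "y1", "l2", "y2")`.
#' @export
expected_pair_covariance <- function(params, group, check = TRUE) {
  if (check) validate_ace_params(params)
  if (!group %in% GROUPS_PAIR)
    stop("unknown zygosity-sex group: ", group)
  sx <- group_sexes(group)
  P1 <- params$paths[[sx[1]]]
  P2 <- params$paths[[sx[2]]]
  W1 <- tcrossprod(P1$a) + tcrossprod(P1$c) + tcrossprod(P1$e)
  W2 <- tcrossprod(P2$a) + tcrossprod(P2$c) + tcrossprod(P2$e)
  X <- switch(group,
    MZM = , MZF = tcrossprod(P1$a) + tcrossprod(P1$c),
    DZM = , DZF = 0.5 * tcrossprod(P1$a) + tcrossprod(P1$c),
    DZOS = P1$a %*% params$G %*% t(P2$a) + P1$c %*% params$H %*% t(P2$c)
  )
  S <- matrix(0, 4, 4, dimnames = list(c("l1", "y1", "l2", "y2"),
                                       c("l1", "y1", "l2", "y2")))
  S[1:2, 1:2] <- W1
  S[3:4, 3:4] <- W2
  S[1:2, 3:4] <- X
  S[3:4, 1:2] <- t(X)
  if (check) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop("implied pair covariance is not positive semi-definite")
  }
  S
}

# Within-person 2x2 covariance (liability, continuous) for one sex.
within_person_cov <- function(params, sex) {
  P <- params$paths[[sex]]
  tcrossprod(P$a) + tcrossprod(P$c) + tcrossprod(P$e)
}

#' Model-implied moments for a family
#'
#' Mean vector, latent covariance and per-member liability thresholds for a
#' twin pair or singleton. Liability means are fixed at 0; the continuous
#' trait has mean `mu` for the member's sex; the threshold of member i is
#' `t_sex + beta_age * (age_i - age_center)`.
#'
#' @param params An `ace_params` parameter set.
#' @param group `"MZM"`, `"MZF"`, `"DZM"`, `"DZF"`, `"DZOS"`, or `"SGL"`.
#' @param ages Numeric vector of member ages (length 2, or 1 for singletons).
#' @param sex Required for `group = "SGL"`: `"M"` or `"F"`.
#' @return A list with `mean`, `cov` and `thresholds`.
#' @export
implied_moments <- function(params, group, ages, sex = NULL) {
  if (group == GROUP_SGL) {
    if (is.null(sex)) stop("sex is required for singletons")
    stopifnot(length(ages) == 1)
    list(mean = c(0, unname(params$mu[[sex]])),
         cov = within_person_cov(params, sex),
         thresholds = unname(params$thresholds[[sex]]) +
           params$beta_age * (ages - params$age_center))
  } else {
    stopifnot(length(ages) == 2)
    sx <- group_sexes(group)
    list(mean = c(0, unname(params$mu[[sx[1]]]), 0, unname(params$mu[[sx[2]]])),
         cov = expected_pair_covariance(params, group, check = FALSE),
         thresholds = unname(params$thresholds[sx]) +
           params$beta_age * (ages - params$age_center))
  }
}
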