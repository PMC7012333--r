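# Synthetic twin-cohort generator.

#' Simulate a twin/singleton cohort under the ACE sex-limitation model
#'
#' Draws latent (liability, continuous-trait) vectors per family from the
#' model-implied covariance of each zygosity-sex group, applies the
#' age-dependent liability threshold to produce the dichotomous trait, and
#' emits the continuous trait on a skewed score scale: the latent trait `x`
#' is normal on the log scale and is emitted as `exp(x) - 1` (default,
#' continuous), or rounded and clipped to the integer 0-63 questionnaire
#' range with `bdi = "integer"`. Twin-pair members share their age.
#' Deterministic given `params$seed`; each group uses a substream derived
#' from it.
#'
#' @param params A [sim_params()] object.
#' @param bdi `"continuous"` (default) or `"integer"` emission of the
#'   skewed score.
#' @param debug_latents If `TRUE`, include the latent liability and latent
#'   continuous trait as extra columns.
#' @return A data.frame with columns `family_id`, `member_index`, `group`,
#'   `sex`, `age`, `t2dm`, `bdi` (plus `liability`, `latent_score` when
#'   `debug_latents = TRUE`).
#' @examples
#' p <- sim_params(n = c(MZM = 0, MZF = 30, DZM = 0, DZF = 20, DZOS = 0, SGL = 10))
#' head(simulate_cohort(p))
#' @export
simulate_cohort <- function(params, bdi = c("continuous", "integer"),
                            debug_latents = FALSE) {
  stopifnot(inherits(params, "sim_params"))
  bdi <- match.arg(bdi)
  pieces <- list()
  groups <- c(GROUPS_PAIR, GROUP_SGL)
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    n <- as.integer(params$n[[g]])
    if (n <= 0) next
    set.seed((params$seed + 7919L * gi) %% .Machine$integer.max)
    ages <- rtruncnorm(n, params$age[["mean"]], params$age[["sd"]],
                       params$age[["min"]], params$age[["max"]])
    if (g == GROUP_SGL) {
      sexes <- rep_len(c("M", "F"), n)
      lat <- matrix(NA_real_, n, 2)
      for (s in c("M", "F")) {
        idx <- which(sexes == s)
        if (!length(idx)) next
        S <- within_person_cov(params, s)
        Z <- matrix(stats::rnorm(2 * length(idx)), ncol = 2) %*% chol(S)
        lat[idx, ] <- sweep(Z, 2, c(0, params$mu[[s]]), "+")
      }
      thr <- unname(params$thresholds[sexes]) +
        params$beta_age * (ages - params$age_center)
      pieces[[g]] <- data.frame(
        family_id = sprintf("SGL-%05d", seq_len(n)),
        member_index = 1L, group = g, sex = sexes, age = ages,
        liability = lat[, 1], latent_score = lat[, 2],
        t2dm = as.integer(lat[, 1] > thr),
        stringsAsFactors = FALSE
      )
    } else {
      S <- expected_pair_covariance(params, g, check = FALSE)
      sx <- group_sexes(g)
      mu <- c(0, params$mu[[sx[1]]], 0, params$mu[[sx[2]]])
      Z <- matrix(stats::rnorm(4 * n), ncol = 4) %*% chol(S)
      Z <- sweep(Z, 2, mu, "+")
      age2 <- rep(ages, each = 2)
      sex2 <- rep(sx, times = n)
      thr <- unname(params$thresholds[sex2]) +
        params$beta_age * (age2 - params$age_center)
      liab <- as.vector(t(Z[, c(1, 3)]))
      scor <- as.vector(t(Z[, c(2, 4)]))
      pieces[[g]] <- data.frame(
        family_id = rep(sprintf("%s-%04d", g, seq_len(n)), each = 2),
        member_index = rep(1:2, times = n), group = g, sex = sex2,
        age = age2, liability = liab, latent_score = scor,
        t2dm = as.integer(liab > thr),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out$bdi <- if (bdi == "integer") {
    pmin(63, pmax(0, round(expm1(out$latent_score))))
  } else {
    expm1(out$latent_score)
  }
  if (!debug_latents) out$liability <- out$latent_score <- NULL
  out[, c("family_id", "member_index", "group", "sex", "age", "t2dm", "bdi",
          intersect(c("liability", "latent_score"), names(out)))]
}

#' Read or write a cohort CSV
#'
#' The CSV schema is the output of [simulate_cohort()]: `family_id`,
#' `member_index`, `group` (MZM/MZF/DZM/DZF/DZOS/SGL), `sex` (M/F), `age`,
#' `t2dm` (0/1), `bdi`; optional extra columns (e.g. `fpg`, `hba1c`, latent
#' debug columns) are carried through.
#'
#' @param x Cohort data.frame (for writing).
#' @param path File path.
#' @return `read_cohort()` returns a data.frame; `write_cohort()` returns
#'   `path` invisibly.
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("family_id", "member_index", "group", "sex", "age", "t2dm", "bdi")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("cohort CSV missing columns: ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(unique(x$group), c(GROUPS_PAIR, GROUP_SGL))
  if (length(bad)) stop("unknown group labels: ", paste(bad, collapse = ", "))
  x
}

#' @rdname read_cohort
#' @export
write_cohort <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
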