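# Phenotype preparation: depression-score residualization, glycemic
# cross-classification, and family assembly for the likelihood.

#' Log-transform and residualize the depression score
#'
#' Computes the analysis variable for the continuous trait: the residual of
#' `log(bdi + 1)` (or of the raw score with `transform = "none"`) from an
#' ordinary least-squares regression on age and sex, fitted jointly over all
#' individuals with a non-missing score. Residuals have mean 0 and are
#' orthogonal to age and the sex indicator. The excess kurtosis of the raw
#' and residualized scores is attached as attribute `"kurtosis"` (and
#' reported with `report_kurtosis = TRUE`).
#'
#' @param records Cohort data.frame with columns `bdi`, `age`, `sex`.
#' @param transform `"log1p"` (default) or `"none"`.
#' @param report_kurtosis If `TRUE`, message the raw and residual excess
#'   kurtosis.
#' @return `records` with a new numeric column `y` (NA where `bdi` is
#'   missing), with attribute `"kurtosis"`.
#' @export
transform_bdi <- function(records, transform = c("log1p", "none"),
                          report_kurtosis = FALSE) {
  transform <- match.arg(transform)
  stopifnot(all(c("bdi", "age", "sex") %in% names(records)))
  obs <- !is.na(records$bdi)
  if (sum(obs) == 0) stop("all depression scores are missing")
  if (sum(obs) < 10) stop("need at least 10 non-missing depression scores")
  if (any(is.na(records$age[obs])) || any(is.na(records$sex[obs])))
    stop("age and sex must be non-missing where the score is present")
  if (any(records$bdi[obs] <= -1)) stop("scores must exceed -1 for log(x+1)")
  v <- if (transform == "log1p") log1p(records$bdi[obs]) else records$bdi[obs]
  kraw <- excess_kurtosis(v)
  if (stats::var(v) == 0) {
    warning("constant depression score; residuals are all 0")
    res <- rep(0, sum(obs))
  } else {
    dat <- data.frame(v = v, age = records$age[obs],
                      sex = factor(records$sex[obs]))
    fml <- if (nlevels(dat$sex) > 1) v ~ age + sex else v ~ age
    res <- stats::residuals(stats::lm(fml, data = dat))
  }
  records$y <- NA_real_
  records$y[obs] <- res
  kres <- excess_kurtosis(res)
  attr(records, "kurtosis") <- c(raw = kraw, residual = kres)
  if (report_kurtosis)
    message(sprintf("excess kurtosis: raw = %.2f, residual = %.2f",
                    kraw, kres))
  records
}

#' Classify glycemic status against diagnostic cutoffs
#'
#' Flags an individual as above the diabetes diagnostic cutoffs when
#' HbA1c >= 48 mmol/mol (IFCC) or fasting plasma glucose >= 7.0 mmol/L; 0
#' when all available markers are below both cutoffs; `NA` (indeterminate)
#' when neither marker is available. Both cutoffs are inclusive.
#'
#' @param hba1c HbA1c in mmol/mol (IFCC); NA allowed.
#' @param fpg Fasting plasma glucose in mmol/L; NA allowed.
#' @param hba1c_cutoff,fpg_cutoff Diagnostic cutoffs (48 mmol/mol,
#'   7.0 mmol/L).
#' @return Integer vector: 1 above cutoff, 0 below, NA indeterminate.
#' @examples
#' classify_glycemia(c(48, 38.8, NA, NA), c(5.0, 5.6, 7.0, NA))
#' @export
classify_glycemia <- function(hba1c, fpg, hba1c_cutoff = 48,
                              fpg_cutoff = 7.0) {
  n <- max(length(hba1c), length(fpg))
  hba1c <- rep_len(as.numeric(hba1c), n)
  fpg <- rep_len(as.numeric(fpg), n)
  if (any(hba1c < 0, na.rm = TRUE) || any(fpg < 0, na.rm = TRUE))
    stop("biomarker values must be non-negative")
  above <- (!is.na(hba1c) & hba1c >= hba1c_cutoff) |
    (!is.na(fpg) & fpg >= fpg_cutoff)
  out <- ifelse(above, 1L, 0L)
  out[is.na(hba1c) & is.na(fpg)] <- NA_integer_
  out
}

#' Cross-classify self-reported diagnosis against biomarker status
#'
#' For self-reported cases and non-cases separately, counts how many
#' individuals have at least one biomarker available and how many of those
#' are at or above a diagnostic cutoff ([classify_glycemia()]).
#'
#' @param records Data.frame with column `t2dm` (0/1/NA) and optional
#'   `hba1c`, `fpg` columns.
#' @return Data.frame with rows for self-report 1 and 0: `n`,
#'   `n_with_samples`, `n_above_cutoff`, `prop_above`.
#' @export
venn_summary <- function(records) {
  hba1c <- records$hba1c %||% rep(NA_real_, nrow(records))
  fpg <- records$fpg %||% rep(NA_real_, nrow(records))
  cls <- if (nrow(records)) classify_glycemia(hba1c, fpg) else integer(0)
  out <- do.call(rbind, lapply(c(1L, 0L), function(sr) {
    sel <- !is.na(records$t2dm) & records$t2dm == sr
    with_samp <- sel & !is.na(cls)
    data.frame(self_report = sr, n = sum(sel),
               n_with_samples = sum(with_samp),
               n_above_cutoff = sum(with_samp & cls == 1L))
  }))
  out$prop_above <- ifelse(out$n_with_samples > 0,
                           out$n_above_cutoff / out$n_with_samples, NA_real_)
  out
}

#' Assemble individual records into likelihood-ready families
#'
#' Groups records by family, orders opposite-sex pairs male-first, turns
#' singletons into one-member families, and keeps partially missing
#' phenotypes (the FIML likelihood marginalizes them; no record is dropped).
#' The continuous analysis variable is taken from column `y` (from
#' [transform_bdi()]); if absent, all `y` are treated as missing.
#'
#' @param records Cohort data.frame (`family_id`, `member_index`, `group`,
#'   `sex`, `age`, `t2dm`, optionally `y`).
#' @return An object of class `twin_families`: a list with a wide per-family
#'   data.frame (`$wide`) and the group counts.
#' @export
pair_assembly <- function(records) {
  need <- c("family_id", "member_index", "group", "sex", "age", "t2dm")
  stopifnot(all(need %in% names(records)))
  if (!"y" %in% names(records)) records$y <- NA_real_
  bad <- setdiff(unique(records$group), c(GROUPS_PAIR, GROUP_SGL))
  if (length(bad)) stop("unknown group labels: ", paste(bad, collapse = ", "))
  counts <- table(records$family_id)
  if (any(counts > 2)) stop("families with more than 2 members: ",
                            paste(names(counts)[counts > 2], collapse = ", "))
  ord <- order(records$family_id, records$member_index)
  r <- records[ord, ]
  dup <- tapply(r$member_index, r$family_id,
                function(m) length(m) == 2 && m[1] == m[2])
  if (any(unlist(dup))) stop("duplicate member_index within family")
  one_group <- tapply(r$group, r$family_id,
                      function(g) length(unique(g)) == 1)
  if (!all(unlist(one_group))) stop("inconsistent group within family")

  first <- !duplicated(r$family_id)
  i1 <- which(first)
  has2 <- c(diff(i1), nrow(r) - i1[length(i1)] + 1) == 2
  i2 <- ifelse(has2, i1 + 1, NA_integer_)
  w <- data.frame(
    family_id = r$family_id[i1], group = r$group[i1],
    sex1 = r$sex[i1], sex2 = r$sex[i2],
    age1 = r$age[i1], age2 = r$age[i2],
    d1 = r$t2dm[i1], d2 = r$t2dm[i2],
    y1 = r$y[i1], y2 = r$y[i2],
    stringsAsFactors = FALSE
  )
  # pair groups must have 2 members with consistent sexes
  pair <- w$group %in% GROUPS_PAIR
  if (any(pair & is.na(w$sex2)))
    stop("twin-pair family with a single member; label it SGL or add member")
  for (g in intersect(unique(w$group), GROUPS_PAIR)) {
    sx <- group_sexes(g)
    rows <- which(w$group == g)
    if (g == "DZOS") {
      flip <- w$sex1[rows] == "F"
      if (any(w$sex1[rows] == w$sex2[rows]))
        stop("DZOS family with same-sex members")
      fr <- rows[flip]
      if (length(fr)) {
        w[fr, c("sex1", "sex2")] <- w[fr, c("sex2", "sex1")]
        w[fr, c("age1", "age2")] <- w[fr, c("age2", "age1")]
        w[fr, c("d1", "d2")] <- w[fr, c("d2", "d1")]
        w[fr, c("y1", "y2")] <- w[fr, c("y2", "y1")]
      }
    } else if (!all(w$sex1[rows] == sx[1] & w$sex2[rows] == sx[2])) {
      stop("sex inconsistent with group label in group ", g)
    }
  }
  if (any(w$group == GROUP_SGL & !is.na(w$sex2)))
    stop("singleton family with two members")
  structure(list(wide = w, n_groups = table(w$group)),
            class = "twin_families")
}

#' @export
print.twin_families <- function(x, ...) {
  cat("Twin family data:", nrow(x$wide), "families\n")
  print(x$n_groups)
  n_obs <- sum(!is.na(unlist(x$wide[, c("d1", "d2", "y1", "y2")])))
  cat("observed data values:", n_obs, "\n")
  invisible(x)
}

#' Prepare a raw cohort for model fitting
#'
#' Convenience wrapper: [transform_bdi()] then [pair_assembly()].
#'
#' @param records Cohort data.frame.
#' @param ... Passed to [transform_bdi()].
#' @return A `twin_families` object.
#' @export
prepare_cohort <- function(records, ...) {
  pair_assembly(transform_bdi(records, ...))
}
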