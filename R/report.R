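# Plain-text report rendering.

#' Render a model-fitting report
#'
#' Produces a deterministic, human-readable report: the model-ladder fit
#' table (-2LL, df, AIC), the comparison table, the per-sex standardized
#' variance decomposition of the selected (or supplied) fit with percentages
#' rounded to whole numbers, and the selection decision trail.
#'
#' @param fits A named list of `ace_fit` objects, or an `ace_ladder`.
#' @param decomps Optional named list of `ace_decomposition` objects keyed
#'   by variant (computed for the selected fit if omitted).
#' @param comparisons Optional comparison data.frame; taken from the ladder
#'   when `fits` is an `ace_ladder`.
#' @return Character vector of report lines (also printed invisibly usable
#'   with [writeLines()]).
#' @export
render_report <- function(fits, decomps = NULL, comparisons = NULL) {
  if (inherits(fits, "ace_ladder")) {
    ladder <- fits
    fits <- ladder$fits
    comparisons <- comparisons %||% ladder$comparisons
    selection <- ladder$selection
  } else {
    if (inherits(fits, "ace_fit")) fits <- stats::setNames(list(fits),
                                                           fits$variant)
    selection <- if (!is.null(comparisons) && nrow(comparisons %||% data.frame()))
      select_best(comparisons) else select_best(fits[[1]])
  }
  ln <- character(0)
  push <- function(...) ln <<- c(ln, sprintf(...))
  push("Bivariate liability-threshold ACE sex-limitation analysis")
  push("=========================================================")
  push("")
  push("Model fit statistics")
  push("%-9s %12s %8s %12s %s", "model", "-2LL", "df", "AIC", "converged")
  for (nm in names(fits)) {
    f <- fits[[nm]]
    push("%-9s %12.2f %8d %12.2f %s", f$variant, f$minus2ll, f$df, f$aic,
         if (f$converged) "yes" else "NO")
  }
  if (!is.null(comparisons) && nrow(comparisons)) {
    push("")
    push("Model comparisons")
    push("%-9s vs %-9s %10s %4s %10s %10s", "nested", "reference",
         "chi2", "ddf", "p", "dAIC")
    for (i in seq_len(nrow(comparisons))) {
      r <- comparisons[i, ]
      push("%-9s vs %-9s %10.3f %4d %10.4g %10.2f", r$nested, r$reference,
           r$chi2, r$delta_df, r$p_value, r$delta_aic)
    }
  }
  push("")
  push("Selected model: %s", selection$selected)
  for (t in selection$trail) push("  - %s", t)
  sel_fit <- fits[[selection$selected]]
  if (!is.null(sel_fit) && !is.null(sel_fit$params)) {
    dec <- (decomps[[selection$selected]] %||% variance_decomposition(sel_fit))
    push("")
    push("Standardized variance components (selected model)")
    for (s in names(dec)) {
      d <- dec[[s]]
      push("  sex %s, liability trait:  a2 = %.0f%%, c2 = %.0f%%, e2 = %.0f%%",
           s, 100 * d$components["A", 1], 100 * d$components["C", 1],
           100 * d$components["E", 1])
      push("  sex %s, continuous trait: a2 = %.0f%%, c2 = %.0f%%, e2 = %.0f%%",
           s, 100 * d$components["A", 2], 100 * d$components["C", 2],
           100 * d$components["E", 2])
      push("  sex %s: rA = %.2f, rC = %.2f, rE = %.2f; r_ph = %.2f (bridges A %.3f, C %.3f, E %.3f)",
           s, d$rA, d$rC, d$rE, d$bridges["r_ph"],
           d$bridges["A"], d$bridges["C"], d$bridges["E"])
    }
  }
  ln
}
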