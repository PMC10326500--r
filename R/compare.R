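#' Compare two proteins for thermostability and hydrophobicity
#'
#' Thermostability is judged on the aliphatic index and hydrophobicity on
#' GRAVY. Each verdict is `"first"`, `"second"` or (within `tolerance`)
#' `"tie"`, rendered as the relational symbols `>`, `<`, `=` for the
#' report template. Both reports must have GRAVY available; a report from
#' an ambiguous sequence is incomparable.
#'
#' @param r1,r2 `phys_chem_report` objects.
#' @param tolerance Absolute difference below which a tie is declared.
#' @return A `comparison_result`: list with `report_1`, `report_2`,
#'   `thermostability_verdict`, `hydrophobicity_verdict` and named
#'   character `symbols`.
#' @export
#' @examples
#' cmp <- compare_reports(compute_report("AVIL"), compute_report("GGGG"))
#' cmp$symbols
compare_reports <- function(r1, r2, tolerance = 1e-9) {
  for (r in list(r1, r2)) {
    if (!inherits(r, "phys_chem_report")) {
      pp_stop("protprops_error_invalid_input", "inputs must be phys_chem_report objects")
    }
  }
  missing1 <- names(r1$unavailable)
  missing2 <- names(r2$unavailable)
  if ("gravy" %in% missing1 || "gravy" %in% missing2) {
    who <- if ("gravy" %in% missing1) "first" else "second"
    pp_stop("protprops_error_incomparable",
            sprintf("incomparable: gravy unavailable for the %s report", who))
  }
  verdict <- function(a, b) {
    if (abs(a - b) <= tolerance) "tie" else if (a > b) "first" else "second"
  }
  sym <- c(first = ">", second = "<", tie = "=")
  tv <- verdict(r1$aliphatic_index, r2$aliphatic_index)
  hv <- verdict(r1$gravy, r2$gravy)
  structure(list(
    report_1 = r1, report_2 = r2,
    thermostability_verdict = tv,
    hydrophobicity_verdict = hv,
    symbols = c(thermostability = unname(sym[tv]),
                hydrophobicity = unname(sym[hv]))
  ), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("thermostability (aliphatic index): Protein-1 %s Protein-2 (%.2f vs %.2f)\n",
              x$symbols[["thermostability"]],
              x$report_1$aliphatic_index, x$report_2$aliphatic_index))
  cat(sprintf("hydrophobicity (GRAVY):            Protein-1 %s Protein-2 (%.3f vs %.3f)\n",
              x$symbols[["hydrophobicity"]],
              x$report_1$gravy, x$report_2$gravy))
  invisible(x)
}

#' Per-residue composition differences between two proteins
#'
#' The data behind the head-to-head overlay plot: mole percents of both
#' profiles over the canonical 20-residue axis (alphabetical three-letter
#' order) and their difference. Residues absent from both sequences appear
#' with zeros.
#'
#' @param p1,p2 `composition_profile` objects.
#' @param tables Constant tables (supplies three-letter names).
#' @return Data frame with columns `residue` (three-letter name),
#'   `percent_1`, `percent_2`, `delta` (= percent_1 - percent_2), one row
#'   per canonical residue.
#' @export
#' @examples
#' composition_delta(residue_composition("AAAA"), residue_composition("GGGG"))
composition_delta <- function(p1, p2, tables = default_tables()) {
  for (p in list(p1, p2)) {
    if (!inherits(p, "composition_profile")) {
      pp_stop("protprops_error_invalid_input", "inputs must be composition_profile objects")
    }
  }
  pct <- function(p, r) if (r %in% names(p$mole_percent)) p$mole_percent[[r]] else 0
  a <- vapply(CANONICAL20, pct, numeric(1), p = p1)
  b <- vapply(CANONICAL20, pct, numeric(1), p = p2)
  data.frame(residue = unname(tables$residue_name3[CANONICAL20]),
             percent_1 = unname(a), percent_2 = unname(b),
             delta = unname(a - b))
}
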