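# Numeric display precisions: MW/pI/AI two decimals, GRAVY three,
# composition percents one. Mirrors the ExPASy-style report conventions.
fmt_mw <- function(x) sprintf("%.2f", x)
fmt_pi <- function(x) sprintf("%.2f", x)
fmt_ai <- function(x) sprintf("%.2f", x)
fmt_gravy <- function(x) sprintf("%.3f", x)
fmt_pct <- function(x) sprintf("%.1f", x)

# Three-letter display name for any residue, including ambiguity codes.
residue_name3 <- function(r, tables = default_tables()) {
  extra <- c(B = "Asx", X = "Xaa", Z = "Glx")
  ifelse(r %in% names(tables$residue_name3), tables$residue_name3[r], extra[r])
}

report_section <- function(report, tables = default_tables()) {
  lines <- character(0)
  add <- function(...) lines <<- c(lines, sprintf(...))
  id <- if (nzchar(report$sequence$seq_id)) report$sequence$seq_id else "(unnamed)"
  add("Sequence: %s", id)
  blocks <- chunk_sequence(report$sequence)$blocks
  for (i in seq(1, length(blocks), by = 6)) {
    j <- min(i + 5, length(blocks))
    add("  %s", paste(blocks[i:j], collapse = " "))
  }
  add("Number of amino acids: %d", report$n_residues)
  if (is.na(report$molecular_weight)) {
    add("Molecular weight (Da): unavailable: %s",
        report$unavailable[["molecular_weight"]])
  } else {
    add("Molecular weight (Da): %s%s", fmt_mw(report$molecular_weight),
        if (report$mw_approximate) " (approximate: B/Z averaged)" else "")
  }
  add("Theoretical pI: %s", fmt_pi(report$theoretical_pi))
  add("Amino acid composition:")
  cn <- names(report$composition$counts)
  for (r in cn) {
    add("  %-3s %5d %6s", residue_name3(r, tables),
        report$composition$counts[[r]],
        fmt_pct(report$composition$mole_percent[[r]]))
  }
  add("Total number of negatively charged residues (Asp + Glu): %d",
      report$n_negative)
  add("Total number of positively charged residues (Arg + Lys): %d",
      report$n_positive)
  if (is.null(report$atomic)) {
    add("Atomic composition: unavailable: %s", report$unavailable[["atomic"]])
  } else {
    add("Atomic composition:")
    full <- c(C = "Carbon", H = "Hydrogen", N = "Nitrogen", O = "Oxygen",
              S = "Sulfur")
    for (e in names(report$atomic$atoms)) {
      add("  %-8s %s %6d", full[[e]], e, as.integer(report$atomic$atoms[[e]]))
    }
    add("Formula: %s", report$atomic$formula)
    add("Total number of atoms: %d", as.integer(report$atomic$total_atoms))
  }
  add("Aliphatic index: %s", fmt_ai(report$aliphatic_index))
  if (is.na(report$gravy)) {
    add("Grand average of hydropathicity (GRAVY): unavailable: %s",
        report$unavailable[["gravy"]])
  } else {
    add("Grand average of hydropathicity (GRAVY): %s", fmt_gravy(report$gravy))
  }
  lines
}

#' Render the plain-text parameter report
#'
#' Produces the .txt report: one parameter section per protein (sequence in
#' 10-residue blocks, residue count, molecular weight, pI, the three-column
#' composition table, charged-residue counts, atomic composition with
#' formula and total atoms, aliphatic index, GRAVY) and, when two reports
#' plus a comparison are given, a final comparison section with the
#' `>`/`<`/`=` verdicts. Unavailable fields render as explicit
#' `unavailable: <reason>` lines, never silently dropped. Rendering is
#' deterministic: identical inputs yield byte-identical text.
#'
#' @param reports A `phys_chem_report` or a list of one or two.
#' @param comparison Optional `comparison_result`; only valid with two
#'   reports.
#' @param tables Constant tables.
#' @return A `report_document`: list with `text` (single string) and
#'   `sections` (list of character vectors).
#' @export
render_text_report <- function(reports, comparison = NULL,
                               tables = default_tables()) {
  if (inherits(reports, "phys_chem_report")) reports <- list(reports)
  if (length(reports) < 1L || length(reports) > 2L) {
    pp_stop("protprops_error_invalid_input", "one or two reports required")
  }
  if (!is.null(comparison) && length(reports) != 2L) {
    pp_stop("protprops_error_invalid_input",
            "a comparison requires exactly two reports")
  }
  sections <- list()
  for (i in seq_along(reports)) {
    header <- sprintf("=== Protein-%d ===", i)
    sections[[length(sections) + 1L]] <-
      c(header, report_section(reports[[i]], tables))
  }
  if (!is.null(comparison)) {
    sections[[length(sections) + 1L]] <- c(
      "=== Comparison ===",
      sprintf("Thermostability (aliphatic index): Protein-1 %s Protein-2",
              comparison$symbols[["thermostability"]]),
      sprintf("Hydrophobicity (GRAVY): Protein-1 %s Protein-2",
              comparison$symbols[["hydrophobicity"]]))
  }
  text <- paste0(paste(unlist(sections), collapse = "\n"), "\n")
  structure(list(text = text, sections = sections), class = "report_document")
}

#' @export
print.report_document <- function(x, ...) {
  cat(x$text)
  invisible(x)
}

#' Render reports as tab-separated values
#'
#' One row per sequence with a fixed column set: `id`, `n_residues`, `mw`,
#' `pi`, `n_negative`, `n_positive`, `aliphatic_index`, `gravy`, `formula`,
#' `total_atoms`, `ambiguous`. Unavailable values render as `NA`. Numeric
#' columns use the same precisions as the text report.
#'
#' @param reports A `phys_chem_report` or a list of them.
#' @return Character scalar: TSV text with a header row.
#' @export
render_tsv <- function(reports) {
  if (inherits(reports, "phys_chem_report")) reports <- list(reports)
  if (length(reports) < 1L) {
    pp_stop("protprops_error_invalid_input", "at least one report required")
  }
  cols <- c("id", "n_residues", "mw", "pi", "n_negative", "n_positive",
            "aliphatic_index", "gravy", "formula", "total_atoms", "ambiguous")
  rows <- vapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    id <- if (nzchar(r$sequence$seq_id)) r$sequence$seq_id else sprintf("seq%d", i)
    vals <- c(
      id,
      as.character(r$n_residues),
      if (is.na(r$molecular_weight)) "NA" else fmt_mw(r$molecular_weight),
      fmt_pi(r$theoretical_pi),
      as.character(r$n_negative),
      as.character(r$n_positive),
      fmt_ai(r$aliphatic_index),
      if (is.na(r$gravy)) "NA" else fmt_gravy(r$gravy),
      if (is.null(r$atomic)) "NA" else r$atomic$formula,
      if (is.null(r$atomic)) "NA" else as.character(as.integer(r$atomic$total_atoms)),
      if (r$ambiguous) "TRUE" else "FALSE")
    paste(vals, collapse = "\t")
  }, character(1))
  paste0(paste(c(paste(cols, collapse = "\t"), rows), collapse = "\n"), "\n")
}

#' Write a report document or TSV text to a file
#'
#' @param x A `report_document` or character scalar (e.g. [render_tsv()]
#'   output).
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_report <- function(x, path) {
  text <- if (inherits(x, "report_document")) x$text else x
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(text, con, eos = NULL)
  invisible(path)
}
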