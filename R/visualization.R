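# All chart functions write a PNG and invisibly return the computed plot
# data (bar heights, wedge percentages, series values) so tests can assert
# on numbers rather than pixels; the image is a pure rendering of that data.
# With fixed raster parameters the cairo PNG device is deterministic.

#' Chart styling and raster parameters
#'
#' @param width,height Raster size in pixels.
#' @param res Raster resolution (ppi).
#' @param col_1,col_2 Series colours for protein 1 / protein 2.
#' @return A `chart_spec` list of raster/styling parameters.
#' @export
chart_spec <- function(width = 900, height = 600, res = 96,
                       col_1 = "steelblue", col_2 = "firebrick") {
  structure(list(width = width, height = height, res = res,
                 col_1 = col_1, col_2 = col_2), class = "chart_spec")
}

open_png <- function(path, spec) {
  if (!grepl("\\.png$", path)) {
    pp_stop("protprops_error_invalid_input", "output path must end in .png")
  }
  if (capabilities("cairo")) {
    grDevices::png(path, width = spec$width, height = spec$height,
                   res = spec$res, type = "cairo")
  } else {
    grDevices::png(path, width = spec$width, height = spec$height,
                   res = spec$res)
  }
}

#' Bar chart of amino-acid composition
#'
#' Bars are occurrence counts over the canonical 20-residue axis labelled
#' with three-letter abbreviations (ambiguity codes appended only when
#' present), titled "AMINO ACID COMPOSITION".
#'
#' @param profile A `composition_profile`.
#' @param path Output PNG path.
#' @param spec A [chart_spec()].
#' @param tables Constant tables.
#' @return Invisibly, a list with `labels` and `heights` (the counts).
#' @export
plot_aa_composition <- function(profile, path, spec = chart_spec(),
                                tables = default_tables()) {
  if (!inherits(profile, "composition_profile")) {
    pp_stop("protprops_error_invalid_input", "profile must be a composition_profile")
  }
  heights <- profile$counts
  labels <- unname(residue_name3(names(heights), tables))
  open_png(path, spec)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(6, 4, 3, 1))
  graphics::barplot(heights, names.arg = labels, las = 2, col = spec$col_1,
                    main = "AMINO ACID COMPOSITION",
                    ylab = "Number of repetitions")
  invisible(list(labels = labels, heights = heights))
}

#' Pie chart of atomic composition
#'
#' Five-element (C, H, N, O, S) pie with percentage labels rounded to one
#' decimal, titled "ATOMIC COMPOSITION". Elements with zero atoms are
#' omitted from the pie (a zero-area wedge is unreadable) but listed in the
#' legend with 0.0%.
#'
#' @param atomic An `atomic_composition`.
#' @param path Output PNG path.
#' @param spec A [chart_spec()].
#' @return Invisibly, a list with `percent` (1-decimal, all five elements),
#'   `percent_exact` and `labels`.
#' @export
plot_atomic_composition <- function(atomic, path, spec = chart_spec()) {
  if (!inherits(atomic, "atomic_composition")) {
    pp_stop("protprops_error_plot_unavailable",
            "atomic composition plot unavailable: no atomic composition (ambiguous sequence?)")
  }
  exact <- 100 * atomic$atoms / atomic$total_atoms
  pct <- round(exact, 1)
  labels <- sprintf("%s %.1f%%", names(pct), pct)
  nz <- atomic$atoms > 0
  open_png(path, spec)
  on.exit(grDevices::dev.off())
  cols <- c("grey35", "goldenrod", "steelblue", "firebrick", "seagreen")
  graphics::pie(atomic$atoms[nz], labels = labels[nz], col = cols[nz],
                main = "ATOMIC COMPOSITION")
  graphics::legend("topleft", legend = labels, fill = cols, bty = "n", cex = 0.9)
  invisible(list(percent = pct, percent_exact = exact, labels = labels))
}

#' Overlay line plot of two composition profiles
#'
#' The head-to-head comparison chart: mole percent of each canonical residue
#' for both proteins as two overlapping line series with a legend.
#'
#' @param delta Output of [composition_delta()].
#' @param path Output PNG path.
#' @param spec A [chart_spec()].
#' @return Invisibly, a list with `residues`, `percent_1`, `percent_2`.
#' @export
plot_composition_overlay <- function(delta, path, spec = chart_spec()) {
  if (!is.data.frame(delta) ||
      !all(c("residue", "percent_1", "percent_2") %in% names(delta))) {
    pp_stop("protprops_error_invalid_input",
            "delta must be a composition_delta data frame")
  }
  n <- nrow(delta)
  open_png(path, spec)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(6, 4, 3, 1))
  ylim <- c(0, max(delta$percent_1, delta$percent_2, 5))
  graphics::plot(seq_len(n), delta$percent_1, type = "o", pch = 16,
                 col = spec$col_1, lwd = 2, xaxt = "n", xlab = "",
                 ylab = "Mole percent", ylim = ylim,
                 main = "AMINO ACID COMPOSITION COMPARISON")
  graphics::lines(seq_len(n), delta$percent_2, type = "o", pch = 17,
                  col = spec$col_2, lwd = 2, lty = 2)
  graphics::axis(1, at = seq_len(n), labels = delta$residue, las = 2)
  graphics::legend("topright", legend = c("Protein-1", "Protein-2"),
                   col = c(spec$col_1, spec$col_2), lty = c(1, 2),
                   pch = c(16, 17), bty = "n")
  invisible(list(residues = delta$residue, percent_1 = delta$percent_1,
                 percent_2 = delta$percent_2))
}

#' Verdict panel for the two-protein comparison
#'
#' A drawn (not template-edited) panel with two rows: thermostability
#' (aliphatic index) and hydrophobicity (GRAVY), each rendered as
#' `Protein-1 <symbol> Protein-2` with symbol `>`, `<` or `=`.
#'
#' @param cmp A `comparison_result`.
#' @param path Output PNG path.
#' @param spec A [chart_spec()].
#' @return Invisibly, a list with `rows` (the two rendered lines) and
#'   `symbols`.
#' @export
render_verdict_panel <- function(cmp, path, spec = chart_spec()) {
  if (!inherits(cmp, "comparison_result")) {
    pp_stop("protprops_error_invalid_input", "cmp must be a comparison_result")
  }
  rows <- c(
    thermostability = sprintf("Protein-1  %s  Protein-2",
                              cmp$symbols[["thermostability"]]),
    hydrophobicity = sprintf("Protein-1  %s  Protein-2",
                             cmp$symbols[["hydrophobicity"]]))
  open_png(path, spec)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(1, 1, 3, 1))
  graphics::plot.new()
  graphics::title(main = "THERMOSTABILITY AND HYDROPHOBICITY COMPARISON")
  graphics::text(0.5, 0.72, "More thermostable (aliphatic index)", cex = 1.2)
  graphics::text(0.5, 0.60, rows[["thermostability"]], cex = 1.8, font = 2)
  graphics::text(0.5, 0.38, "More hydrophobic (GRAVY)", cex = 1.2)
  graphics::text(0.5, 0.26, rows[["hydrophobicity"]], cex = 1.8, font = 2)
  invisible(list(rows = rows, symbols = cmp$symbols))
}
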