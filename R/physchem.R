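#' Amino-acid composition of a sequence
#'
#' Counts each residue and converts counts to mole percent
#' (100 x count / length). All 20 canonical residues are always present in
#' the profile (count 0 when absent), listed in alphabetical three-letter
#' order; ambiguity codes B/X/Z are appended only when they occur.
#'
#' @param seq A `protein_sequence` (or raw text).
#' @return A `composition_profile`: list with named integer `counts`,
#'   `length`, and named numeric `mole_percent` (full precision; rounding to
#'   1 decimal happens only in reports and charts).
#' @export
#' @examples
#' residue_composition("AAG")$mole_percent[c("A", "G")]
residue_composition <- function(seq) {
  seq <- as_protein_sequence(seq)
  chars <- seq_chars(seq)
  axis <- c(CANONICAL20, intersect(AMBIGUOUS, unique(chars)))
  counts <- vapply(axis, function(r) sum(chars == r), integer(1))
  n <- length(chars)
  structure(list(counts = counts, length = n,
                 mole_percent = 100 * counts / n),
            class = "composition_profile")
}

#' Average molecular weight of a protein
#'
#' Sum of the average isotopic residue masses plus one water molecule. The
#' ambiguity codes B and Z are assigned the arithmetic mean of their two
#' candidate residues (Asn/Asp and Gln/Glu) and the result is flagged
#' approximate; X has no defensible mass and raises an error.
#'
#' @param seq A `protein_sequence` (or raw text).
#' @param tables Constant tables, see [default_tables()].
#' @return Numeric mass in Da, with attribute `approximate` set to `TRUE`
#'   when B or Z contributed an averaged mass.
#' @export
#' @examples
#' molecular_weight("G")  # ~75.07 Da
molecular_weight <- function(seq, tables = default_tables()) {
  seq <- as_protein_sequence(seq)
  chars <- seq_chars(seq)
  if (any(chars == "X")) {
    pp_stop("protprops_error_mass_undefined",
            "mass undefined: sequence contains unspecified residue X")
  }
  mass <- tables$residue_mass
  mass <- c(mass,
            B = unname((mass[["N"]] + mass[["D"]]) / 2),
            Z = unname((mass[["Q"]] + mass[["E"]]) / 2))
  mw <- sum(mass[chars]) + tables$water_mass
  structure(mw, approximate = any(chars %in% c("B", "Z")))
}

# Ionizable-group multiplicities for a residue character vector: each
# terminus counts once; B/X/Z side chains are treated as non-ionizable.
charge_groups <- function(chars) {
  side <- c("D", "E", "C", "Y", "H", "K", "R")
  n <- vapply(side, function(r) sum(chars == r), numeric(1))
  c(Nterm = 1, Cterm = 1, n)
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch partial-charge model: each basic group g
#' contributes \eqn{n_g / (1 + 10^{pH - pK_g})} and each acidic group
#' \eqn{-n_g / (1 + 10^{pK_g - pH})}, with the termini counting once each.
#' The result is continuous and strictly decreasing in pH.
#'
#' @param seq A `protein_sequence` (or raw text).
#' @param pH Numeric vector of pH values in \[0, 14\].
#' @param tables Constant tables.
#' @return Net charge in elementary charges, one value per pH.
#' @export
#' @examples
#' net_charge("DEKR", 7.0)
net_charge <- function(seq, pH, tables = default_tables()) {
  seq <- as_protein_sequence(seq)
  if (any(pH < 0 | pH > 14)) {
    pp_stop("protprops_error_invalid_input", "pH must be within [0, 14]")
  }
  n <- charge_groups(seq_chars(seq))
  pk <- tables$pk
  sign <- tables$pk_sign
  vapply(pH, function(p) {
    pos <- sum(vapply(names(n)[sign[names(n)] == "basic"], function(g) {
      n[[g]] / (1 + 10^(p - pk[[g]]))
    }, numeric(1)))
    neg <- sum(vapply(names(n)[sign[names(n)] == "acidic"], function(g) {
      n[[g]] / (1 + 10^(pk[[g]] - p))
    }, numeric(1)))
    pos - neg
  }, numeric(1))
}

#' Theoretical isoelectric point
#'
#' The pH at which the modeled net charge is zero, found by bisection on
#' \[0, 14\]. Because the charge function is continuous and strictly
#' decreasing, and the termini guarantee a positive charge at pH 0 and a
#' negative one at pH 14, a unique root always exists.
#'
#' @param seq A `protein_sequence` (or raw text).
#' @param tables Constant tables.
#' @param tol Convergence tolerance: iteration stops when |charge| <= `tol`
#'   or the bracketing interval is narrower than `tol`.
#' @return pI in pH units; `|net_charge(seq, pI)| <= tol`.
#' @export
#' @examples
#' theoretical_pi("AAAA")  # midpoint of the terminal pKs, 5.525
theoretical_pi <- function(seq, tables = default_tables(), tol = 1e-4) {
  seq <- as_protein_sequence(seq)
  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    q <- net_charge(seq, mid, tables)
    if (abs(q) <= tol || (hi - lo) <= tol) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
}

#' Atomic composition, molecular formula and total atom count
#'
#' Per-element (C, H, N, O, S) sums of the residue atom counts over the
#' chain, plus one water (H2, O). Undefined for sequences containing the
#' ambiguity codes B, X or Z, whose elemental makeup cannot be resolved.
#'
#' @param seq A `protein_sequence` (or raw text).
#' @param tables Constant tables.
#' @return An `atomic_composition`: list with named numeric `atoms`
#'   (C, H, N, O, S), `formula` (e.g. `"C2H5NO2"`) and `total_atoms`.
#' @export
#' @examples
#' atomic_composition("G")$formula  # "C2H5NO2"
atomic_composition <- function(seq, tables = default_tables()) {
  seq <- as_protein_sequence(seq)
  chars <- seq_chars(seq)
  amb <- intersect(unique(chars), AMBIGUOUS)
  if (length(amb) > 0L) {
    pp_stop("protprops_error_ambiguous",
            sprintf("atomic composition cannot be estimated: ambiguous residue(s) %s",
                    paste(amb, collapse = ", ")))
  }
  counts <- vapply(CANONICAL20, function(r) sum(chars == r), numeric(1))
  atoms <- drop(counts %*% tables$residue_atoms[CANONICAL20, ]) +
    c(C = 0, H = 2, N = 0, O = 1, S = 0)
  structure(list(atoms = atoms,
                 formula = render_formula(atoms),
                 total_atoms = sum(atoms)),
            class = "atomic_composition")
}

# Canonical formula rendering: elements in C, H, N, O, S order, count
# suffix omitted when 1, zero-count elements omitted.
render_formula <- function(atoms) {
  parts <- vapply(c("C", "H", "N", "O", "S"), function(e) {
    k <- atoms[[e]]
    if (k == 0) "" else if (k == 1) e else paste0(e, format(k, scientific = FALSE))
  }, character(1))
  paste(parts, collapse = "")
}

#' Counts of charged residues
#'
#' Negatively charged = Asp + Glu; positively charged = Arg + Lys. His is
#' deliberately excluded from the positive count, following the classical
#' ProtParam-style definition.
#'
#' @param seq A `protein_sequence` (or raw text).
#' @return Named list with `n_negative` and `n_positive`.
#' @export
#' @examples
#' charged_residue_counts("DEKR")  # 2 negative, 2 positive
charged_residue_counts <- function(seq) {
  seq <- as_protein_sequence(seq)
  chars <- seq_chars(seq)
  list(n_negative = sum(chars %in% c("D", "E")),
       n_positive = sum(chars %in% c("R", "K")))
}

#' Aliphatic index
#'
#' The relative volume occupied by aliphatic side chains,
#' \deqn{AI = X(Ala) + a \cdot X(Val) + b \cdot (X(Ile) + X(Leu))}
#' where X(.) are mole percents and the coefficients are the side-chain
#' volumes relative to alanine (a = 2.9 for Val, b = 3.9 for Ile/Leu). A
#' positive correlate of globular-protein thermostability; range \[0, 390\].
#'
#' @param x A `composition_profile`, `protein_sequence`, or raw text.
#' @param tables Constant tables (supplies the coefficients).
#' @return Dimensionless index.
#' @export
#' @examples
#' aliphatic_index("AVIL")  # 292.5
aliphatic_index <- function(x, tables = default_tables()) {
  profile <- if (inherits(x, "composition_profile")) x else
    residue_composition(as_protein_sequence(x))
  p <- profile$mole_percent
  a <- tables$aliphatic[["a"]]
  b <- tables$aliphatic[["b"]]
  unname(p[["A"]] + a * p[["V"]] + b * (p[["I"]] + p[["L"]]))
}

#' Grand average of hydropathicity (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over all residues; positive values
#' indicate hydrophobic proteins. Undefined when ambiguity codes are
#' present: silently dropping them would change the denominator invisibly,
#' so an error is raised instead.
#'
#' @param seq A `protein_sequence` (or raw text).
#' @param tables Constant tables.
#' @return Mean hydropathy, bounded by the scale's extremes \[-4.5, 4.5\].
#' @export
#' @examples
#' gravy("IR")  # 0
gravy <- function(seq, tables = default_tables()) {
  seq <- as_protein_sequence(seq)
  chars <- seq_chars(seq)
  amb <- intersect(unique(chars), AMBIGUOUS)
  if (length(amb) > 0L) {
    pp_stop("protprops_error_ambiguous",
            sprintf("hydropathy undefined: ambiguous residue(s) %s",
                    paste(amb, collapse = ", ")))
  }
  mean(tables$kd[chars])
}

#' Compute the full physicochemical report for one sequence
#'
#' Assembles every property into one bundle. Sequences containing the
#' ambiguity codes B/X/Z get a partial report: composition, length, pI and
#' charged-residue counts are always computed; molecular weight (if X is
#' present), atomic composition and GRAVY are recorded as unavailable with a
#' reason instead of failing the whole report.
#'
#' @param seq A `protein_sequence` (or raw text).
#' @param tables Constant tables.
#' @return A `phys_chem_report`: list with `sequence`, `n_residues`,
#'   `molecular_weight` (NA when unavailable), `mw_approximate`,
#'   `theoretical_pi`, `composition`, `n_negative`, `n_positive`, `atomic`
#'   (NULL when unavailable), `aliphatic_index`, `gravy` (NA when
#'   unavailable), `ambiguous` flag and named character `unavailable`
#'   mapping missing fields to reasons.
#' @export
#' @examples
#' rep <- compute_report("ACDEFGHIKLMNPQRSTVWY")
#' rep$aliphatic_index
compute_report <- function(seq, tables = default_tables()) {
  seq <- as_protein_sequence(seq)
  chars <- seq_chars(seq)
  composition <- residue_composition(seq)
  charged <- charged_residue_counts(seq)
  unavailable <- character(0)

  mw <- tryCatch(molecular_weight(seq, tables), protprops_error = function(e) {
    unavailable["molecular_weight"] <<- conditionMessage(e)
    NA_real_
  })
  mw_approx <- isTRUE(attr(mw, "approximate"))
  atomic <- tryCatch(atomic_composition(seq, tables),
                     protprops_error = function(e) {
                       unavailable["atomic"] <<- conditionMessage(e)
                       NULL
                     })
  grv <- tryCatch(gravy(seq, tables), protprops_error = function(e) {
    unavailable["gravy"] <<- conditionMessage(e)
    NA_real_
  })

  structure(list(
    sequence = seq,
    n_residues = composition$length,
    molecular_weight = as.numeric(mw),
    mw_approximate = mw_approx,
    theoretical_pi = theoretical_pi(seq, tables),
    composition = composition,
    n_negative = charged$n_negative,
    n_positive = charged$n_positive,
    atomic = atomic,
    aliphatic_index = aliphatic_index(composition, tables),
    gravy = grv,
    ambiguous = any(chars %in% AMBIGUOUS),
    unavailable = unavailable
  ), class = "phys_chem_report")
}

#' @export
print.phys_chem_report <- function(x, ...) {
  cat(render_text_report(list(x))$text)
  invisible(x)
}
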