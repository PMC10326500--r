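#' Load the packaged residue constant tables
#'
#' Reads the numeric tables every property computation depends on: average
#' isotopic residue masses and the water mass, elemental (C/H/N/O/S) counts
#' per residue, pK values of the nine ionizable groups, the Kyte-Doolittle
#' hydropathy scale and the aliphatic-index coefficients. The tables ship as
#' a single human-readable YAML file so that alternates (or deliberately
#' corrupted copies, for testing) can be swapped in.
#'
#' @param path Path to a constants YAML file. Defaults to the file packaged
#'   in `inst/extdata/constants.yaml`.
#' @return An object of class `residue_tables`: a list with elements
#'   `residue_mass` (named numeric, 20 residues, Da), `water_mass` (Da),
#'   `residue_atoms` (20 x 5 integer matrix, columns C/H/N/O/S),
#'   `residue_name3` (named character), `pk` and `pk_sign` (named over the
#'   nine ionizable groups), `kd` (named numeric hydropathy values) and
#'   `aliphatic` (named numeric `a`, `b`).
#' @seealso [validate_tables()] to check the invariants of a loaded set.
#' @export
#' @examples
#' tab <- load_constant_tables()
#' tab$residue_mass[["G"]]
load_constant_tables <- function(path = system.file("extdata", "constants.yaml",
                                                    package = "protprops")) {
  raw <- yaml::read_yaml(path)
  res <- raw$residues
  rn <- names(res)
  mass <- vapply(res, function(r) as.numeric(r$mass), numeric(1))
  atoms <- t(vapply(res, function(r) {
    vapply(c("C", "H", "N", "O", "S"), function(e) as.numeric(r$atoms[[e]]),
           numeric(1))
  }, numeric(5)))
  rownames(atoms) <- rn
  name3 <- vapply(res, function(r) as.character(r$name3), character(1))
  kd <- vapply(res, function(r) as.numeric(r$kd), numeric(1))
  pk <- vapply(raw$pk, function(g) as.numeric(g$value), numeric(1))
  pk_sign <- vapply(raw$pk, function(g) as.character(g$sign), character(1))
  structure(list(
    residue_mass = mass,
    water_mass = as.numeric(raw$water_mass),
    residue_atoms = atoms,
    residue_name3 = name3,
    pk = pk,
    pk_sign = pk_sign,
    kd = kd,
    aliphatic = c(a = as.numeric(raw$aliphatic_coefficients$a),
                  b = as.numeric(raw$aliphatic_coefficients$b))
  ), class = "residue_tables")
}

# Cached default tables; loaded once per session, treated as read-only.
.tables_cache <- new.env(parent = emptyenv())

#' Default constant tables
#'
#' Returns the packaged [load_constant_tables()] result, cached for the
#' session. Every computation takes a `tables` argument defaulting to this.
#' @return A `residue_tables` object.
#' @export
default_tables <- function() {
  if (is.null(.tables_cache$tables)) {
    .tables_cache$tables <- load_constant_tables()
  }
  .tables_cache$tables
}

# Standard atomic weights (IUPAC conventional values) used only for the
# cross-table consistency check, never for molecular-weight computation.
.ATOMIC_WEIGHTS <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, S = 32.06)

#' Validate a set of constant tables
#'
#' Checks every structural invariant of the five tables and their mutual
#' consistency: 20 canonical residues with positive masses, water mass near
#' 18.015 Da, non-negative atom counts with N >= 1 and C >= 2, sulfur only in
#' Cys and Met, nine ionizable groups with pK in (0, 14) and the expected
#' acid/base split, the hydropathy scale bounded by [-4.5, 4.5] with its
#' extremes at Ile and Arg, aliphatic coefficients a = 2.9 and b = 3.9, and
#' the cross-table rule that residue mass + water mass reproduces the free
#' amino acid's elemental mass (from standard atomic weights) within 0.01 Da.
#'
#' @param tables A `residue_tables` object.
#' @return Character vector of violation messages; `character(0)` when the
#'   tables are internally consistent.
#' @export
#' @examples
#' validate_tables(default_tables())  # character(0)
validate_tables <- function(tables = default_tables()) {
  v <- character(0)
  note <- function(msg) v <<- c(v, msg)

  mass <- tables$residue_mass
  if (!setequal(names(mass), CANONICAL20) || length(mass) != 20L) {
    note("MassTable: must have exactly the 20 canonical residues")
  }
  bad <- names(mass)[!is.finite(mass) | mass <= 0]
  for (r in bad) note(sprintf("MassTable: residue %s has non-positive mass", r))
  if (!(tables$water_mass > 18.0 && tables$water_mass < 18.1)) {
    note("MassTable: water_mass outside (18.0, 18.1) Da")
  }

  atoms <- tables$residue_atoms
  if (!setequal(rownames(atoms), CANONICAL20) || nrow(atoms) != 20L) {
    note("AtomTable: must have exactly the 20 canonical residues")
  }
  for (r in rownames(atoms)) {
    a <- atoms[r, ]
    if (any(a < 0)) note(sprintf("AtomTable: residue %s has a negative count", r))
    if (a[["N"]] < 1) note(sprintf("AtomTable: residue %s has N < 1", r))
    if (a[["C"]] < 2) note(sprintf("AtomTable: residue %s has C < 2", r))
    s_ok <- if (r %in% c("C", "M")) a[["S"]] > 0 else a[["S"]] == 0
    if (!s_ok) note(sprintf("AtomTable: residue %s has wrong sulfur count", r))
  }

  pk <- tables$pk
  groups <- c("Nterm", "Cterm", "D", "E", "C", "Y", "H", "K", "R")
  if (!setequal(names(pk), groups)) {
    note("PKSet: must have exactly the 9 ionizable groups")
  } else {
    if (any(pk <= 0 | pk >= 14)) note("PKSet: pK value outside (0, 14)")
    acidic <- names(tables$pk_sign)[tables$pk_sign == "acidic"]
    basic <- names(tables$pk_sign)[tables$pk_sign == "basic"]
    if (!setequal(acidic, c("Cterm", "D", "E", "C", "Y"))) {
      note("PKSet: acidic group set is wrong")
    }
    if (!setequal(basic, c("Nterm", "H", "K", "R"))) {
      note("PKSet: basic group set is wrong")
    }
  }

  kd <- tables$kd
  if (!setequal(names(kd), CANONICAL20)) {
    note("HydropathyScale: must cover exactly the 20 canonical residues")
  } else {
    if (any(kd < -4.5 | kd > 4.5)) note("HydropathyScale: value outside [-4.5, 4.5]")
    if (names(which.max(kd)) != "I") note("HydropathyScale: maximum is not Ile")
    if (names(which.min(kd)) != "R") note("HydropathyScale: minimum is not Arg")
  }

  if (!isTRUE(all.equal(unname(tables$aliphatic), c(2.9, 3.9)))) {
    note("AliphaticCoefficients: a, b must be 2.9 and 3.9")
  }

  # Cross-table: residue mass + water == elemental mass of the free amino acid.
  common <- intersect(names(mass), rownames(atoms))
  for (r in common) {
    free_atoms <- atoms[r, ] + c(C = 0, H = 2, N = 0, O = 1, S = 0)
    elemental <- sum(free_atoms * .ATOMIC_WEIGHTS[colnames(atoms)])
    if (is.finite(mass[[r]]) &&
        abs(mass[[r]] + tables$water_mass - elemental) >= 0.01) {
      note(sprintf(
        "Cross-table: residue %s mass %.4f + water disagrees with elemental mass %.4f",
        r, mass[[r]], elemental))
    }
  }
  v
}
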