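# Seeded synthetic-sequence generation: every module is testable without a
# download. The generator seeds a local RNG stream and restores the global
# state afterwards, so callers' random streams are never disturbed.

with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a random protein sequence
#'
#' Draws residues independently with the given per-residue weights (default
#' uniform over the 20 canonical residues). With probability
#' `ambiguous_rate`, a position is replaced by one of the ambiguity codes
#' B/X/Z (uniformly). The same seed and configuration always yield the same
#' sequence, and the caller's global random stream is left untouched.
#'
#' @param length Number of residues (>= 1).
#' @param weights Optional named non-negative sampling weights over the 20
#'   canonical residues (missing residues get weight 0; not all zero).
#' @param ambiguous_rate Probability in \[0, 1\] that a position carries an
#'   ambiguity code instead of a canonical residue.
#' @param seed Integer seed; `NULL` uses the current random stream.
#' @param seq_id Identifier for the generated record.
#' @return A `protein_sequence`.
#' @export
#' @examples
#' random_sequence(50, seed = 42)
random_sequence <- function(length, weights = NULL, ambiguous_rate = 0,
                            seed = NULL, seq_id = "") {
  if (!is.numeric(length) || length < 1) {
    pp_stop("protprops_error_invalid_input", "length must be >= 1")
  }
  if (ambiguous_rate < 0 || ambiguous_rate > 1) {
    pp_stop("protprops_error_invalid_input", "ambiguous_rate must be in [0, 1]")
  }
  w <- stats::setNames(rep(1, 20), CANONICAL20)
  if (!is.null(weights)) {
    if (is.null(names(weights)) || any(!names(weights) %in% CANONICAL20) ||
        any(weights < 0) || sum(weights) == 0) {
      pp_stop("protprops_error_invalid_input",
              "weights must be named, non-negative over canonical residues, not all zero")
    }
    w[] <- 0
    w[names(weights)] <- weights
  }
  n <- as.integer(length)
  chars <- with_local_seed(seed, {
    base <- sample(CANONICAL20, n, replace = TRUE, prob = w)
    if (ambiguous_rate > 0) {
      amb <- stats::runif(n) < ambiguous_rate
      base[amb] <- sample(AMBIGUOUS, sum(amb), replace = TRUE)
    }
    base
  })
  parse_sequence(paste(chars, collapse = ""), seq_id = seq_id)
}

#' Fixed worked-example sequences
#'
#' The small sequences used throughout the documentation and tests --
#' homopolymers with closed-form aliphatic index and GRAVY, the uniform
#' 20-residue sequence, charged tetrapeptides and an ambiguous example --
#' each with a stable unique id.
#'
#' @return Named list of `protein_sequence` objects.
#' @export
#' @examples
#' names(worked_example_set())
worked_example_set <- function() {
  raw <- c(
    gly = "G",
    aag = "AAG",
    tetra_ala = "AAAA",
    poly_val = "VVVV",
    avil = "AVIL",
    poly_ile = "IIII",
    poly_arg = "RRRR",
    ir = "IR",
    dekr = "DEKR",
    axa = "AXA",
    all20 = "ACDEFGHIKLMNPQRSTVWY",
    poly_lys10 = "KKKKKKKKKK",
    poly_asp10 = "DDDDDDDDDD"
  )
  out <- lapply(names(raw), function(id) parse_sequence(raw[[id]], seq_id = id))
  stats::setNames(out, names(raw))
}
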