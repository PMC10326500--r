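#' Parse raw text into a validated protein sequence
#'
#' Cleans pasted text the way a sequence entry box should: whitespace and
#' digit characters (line numbers from sequence viewers) are stripped and
#' letters uppercased. The result must be a non-empty string over the
#' 23-letter alphabet -- the 20 canonical residues plus the ambiguity codes
#' `B` (Asn/Asp), `X` (unspecified) and `Z` (Gln/Glu). Anything else,
#' including `*` stop characters, is rejected with the offending character
#' and its position in the cleaned sequence.
#'
#' @param raw Character scalar: pasted sequence text.
#' @param seq_id Optional identifier (default empty).
#' @return A `protein_sequence` object: list with `seq_id` and `residues`.
#' @export
#' @examples
#' parse_sequence("mkv lf\n10 aa")$residues  # "MKVLFAA"
parse_sequence <- function(raw, seq_id = "") {
  if (length(raw) != 1L || !is.character(raw)) {
    pp_stop("protprops_error_invalid_input", "raw must be a single character string")
  }
  cleaned <- toupper(gsub("[[:space:][:digit:]]", "", raw))
  if (!nzchar(cleaned)) {
    pp_stop("protprops_error_empty_sequence", "empty sequence after cleaning")
  }
  chars <- strsplit(cleaned, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% ALPHABET23))
  if (length(bad) > 0L) {
    pp_stop("protprops_error_invalid_residue",
            sprintf("invalid residue '%s' at position %d", chars[bad[1]], bad[1]),
            residue = chars[bad[1]], position = bad[1])
  }
  structure(list(seq_id = as.character(seq_id), residues = cleaned),
            class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  id <- if (nzchar(x$seq_id)) x$seq_id else "<unnamed>"
  cat(sprintf("protein_sequence %s (%d residues)\n", id, nchar(x$residues)))
  blocks <- chunk_sequence(x)$blocks
  for (i in seq(1, length(blocks), by = 6)) {
    j <- min(i + 5, length(blocks))
    cat(" ", paste(blocks[i:j], collapse = " "), "\n")
  }
  invisible(x)
}

# residues as a character vector
seq_chars <- function(seq) strsplit(seq$residues, "", fixed = TRUE)[[1]]

as_protein_sequence <- function(x, seq_id = "") {
  if (inherits(x, "protein_sequence")) x else parse_sequence(x, seq_id)
}

#' Read protein sequences from FASTA text or a bare sequence
#'
#' Accepts a file path or literal text. FASTA input (one or more
#' '>'-headed records; parsed with Biostrings) yields one record per header,
#' with the full header text as `seq_id` and body lines concatenated and
#' validated through [parse_sequence()]. Input with no header at all is
#' treated as a single bare sequence with an empty `seq_id` -- the
#' paste-a-sequence convenience.
#'
#' @param input Path to a FASTA file, or a character scalar/vector of text.
#' @return List of `protein_sequence` objects in file order.
#' @export
#' @examples
#' read_fasta(">p1\nMKV\nLFA\n")[[1]]$residues  # "MKVLFA"
read_fasta <- function(input) {
  is_path <- length(input) == 1L && !grepl("[>\n]", input) && file.exists(input)
  text <- if (is_path) readLines(input, warn = FALSE) else
    unlist(strsplit(input, "\n", fixed = TRUE), use.names = FALSE)
  if (length(text) == 0L || !any(nzchar(trimws(text)))) {
    pp_stop("protprops_error_empty_sequence", "empty input")
  }
  if (!any(startsWith(trimws(text), ">"))) {
    return(list(parse_sequence(paste(text, collapse = ""))))
  }
  tf <- tempfile(fileext = ".fasta")
  on.exit(unlink(tf))
  writeLines(text, tf)
  set <- Biostrings::readBStringSet(tf)
  records <- vector("list", length(set))
  for (i in seq_along(set)) {
    id <- names(set)[i]
    body <- as.character(set[[i]])
    if (!nzchar(gsub("[[:space:]]", "", body))) {
      pp_stop("protprops_error_empty_record",
              sprintf("empty record for header '%s'", id))
    }
    records[[i]] <- tryCatch(parse_sequence(body, seq_id = id),
      protprops_error = function(e) {
        pp_stop(class(e)[1], sprintf("record '%s': %s", id, conditionMessage(e)))
      })
  }
  records
}

#' Write protein sequences as FASTA
#'
#' Writes standard FASTA with 60-residue line wrapping. Records with an
#' empty `seq_id` get a synthesized header `seq<i>` (their position in the
#' list), so output is always re-readable.
#'
#' @param records A `protein_sequence` or list of them.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "protein_sequence")) records <- list(records)
  if (length(records) == 0L) {
    pp_stop("protprops_error_invalid_input", "no records to write")
  }
  ids <- vapply(seq_along(records), function(i) {
    id <- records[[i]]$seq_id
    if (nzchar(id)) id else sprintf("seq%d", i)
  }, character(1))
  set <- Biostrings::BStringSet(vapply(records, `[[`, character(1), "residues"))
  names(set) <- ids
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Split a sequence into fixed-width display blocks
#'
#' The report display convention: the residue string is divided into blocks
#' of `block_width` residues (default 10) so positions are easy to count off.
#' The concatenation of the blocks always equals the original sequence.
#'
#' @param seq A `protein_sequence` (or raw text, parsed first).
#' @param block_width Residues per block; must be >= 1.
#' @return A `sequence_blocks` object: list with `blocks` and `block_width`.
#' @export
#' @examples
#' chunk_sequence(parse_sequence("ACDEFGHIKLMNPQRSTVWYACDEF"))$blocks
chunk_sequence <- function(seq, block_width = 10L) {
  seq <- as_protein_sequence(seq)
  if (!is.numeric(block_width) || length(block_width) != 1L || block_width < 1) {
    pp_stop("protprops_error_invalid_input", "block_width must be >= 1")
  }
  block_width <- as.integer(block_width)
  n <- nchar(seq$residues)
  starts <- seq.int(1L, n, by = block_width)
  blocks <- substring(seq$residues, starts, pmin(starts + block_width - 1L, n))
  structure(list(blocks = blocks, block_width = block_width),
            class = "sequence_blocks")
}
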