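test_that("parse_sequence cleans pasted text and validates the alphabet", {
  expect_identical(parse_sequence("mkv lf\n10 aa")$residues, "MKVLFAA")
  expect_identical(parse_sequence("ACDBXZ")$residues, "ACDBXZ")

  err <- expect_error(parse_sequence("ACDJ"),
                      class = "protprops_error_invalid_residue")
  expect_match(conditionMessage(err), "'J'")
  expect_identical(err$position, 4L)

  expect_error(parse_sequence(""), class = "protprops_error_empty_sequence")
  expect_error(parse_sequence(" 12 \n"), class = "protprops_error_empty_sequence")
  expect_error(parse_sequence("MK*V"), class = "protprops_error_invalid_residue")
})

test_that("parse_sequence is idempotent on clean sequences", {
  for (seq in worked_example_set()) {
    expect_identical(parse_sequence(seq$residues)$residues, seq$residues)
  }
})

test_that("read_fasta handles single records, multi-records and bare sequences", {
  one <- read_fasta(">p1\nMKV\nLFA\n")
  expect_length(one, 1)
  expect_identical(one[[1]]$seq_id, "p1")
  expect_identical(one[[1]]$residues, "MKVLFA")

  two <- read_fasta(">a\nMK\n>b\nVL\n")
  expect_identical(vapply(two, `[[`, character(1), "seq_id"), c("a", "b"))
  expect_identical(vapply(two, `[[`, character(1), "residues"), c("MK", "VL"))

  bare <- read_fasta("MKVLFA")
  expect_identical(bare[[1]]$seq_id, "")
  expect_identical(bare[[1]]$residues, "MKVLFA")
})

test_that("read_fasta rejects empty records and propagates residue errors with context", {
  expect_error(read_fasta(">empty\n>b\nVL\n"),
               class = "protprops_error_empty_record")
  err <- expect_error(read_fasta(">bad\nACDJ\n"),
                      class = "protprops_error_invalid_residue")
  expect_match(conditionMessage(err), "bad")
})

test_that("write_fasta wraps at 60 columns and synthesizes headers", {
  long <- parse_sequence(strrep("ACDEFGHIKL", 13), seq_id = "p1")
  tf <- tempfile(fileext = ".fasta")
  write_fasta(long, tf)
  lines <- readLines(tf)
  expect_identical(lines[1], ">p1")
  expect_identical(nchar(lines[2]), 60L)

  anon <- parse_sequence("MKVLFA")
  write_fasta(list(anon), tf)
  expect_identical(readLines(tf)[1], ">seq1")
})

test_that("FASTA round-trip preserves 100 seeded random records", {
  records <- lapply(1:100, function(i) {
    random_sequence(sample(1:80, 1), seed = 5000 + i,
                    seq_id = sprintf("rec%03d", i))
  })
  tf <- tempfile(fileext = ".fasta")
  write_fasta(records, tf)
  back <- read_fasta(tf)
  expect_identical(vapply(back, `[[`, character(1), "seq_id"),
                   vapply(records, `[[`, character(1), "seq_id"))
  expect_identical(vapply(back, `[[`, character(1), "residues"),
                   vapply(records, `[[`, character(1), "residues"))
})

test_that("chunk_sequence produces fixed-width blocks that concatenate to the input", {
  v <- chunk_sequence(random_sequence(25, seed = 1))
  expect_identical(nchar(v$blocks), c(10L, 10L, 5L))

  exact <- chunk_sequence(random_sequence(10, seed = 2))
  expect_length(exact$blocks, 1)

  for (i in 1:20) {
    s <- random_sequence(sample(1:200, 1), seed = 600 + i)
    w <- sample(1:15, 1)
    v <- chunk_sequence(s, w)
    expect_identical(paste(v$blocks, collapse = ""), s$residues)
    expect_true(all(nchar(head(v$blocks, -1)) == w))
  }

  expect_error(chunk_sequence(random_sequence(5, seed = 3), 0),
               class = "protprops_error_invalid_input")
})
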