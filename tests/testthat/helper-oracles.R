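# Independent naive per-character accumulation oracles. These deliberately
# walk the sequence one character at a time with scalar arithmetic, staying
# independent of the package's vectorised computation paths (which use
# counts and matrix products), while reading the same constant tables.

oracle_chars <- function(seq) strsplit(seq$residues, "", fixed = TRUE)[[1]]

oracle_mw <- function(seq, tables = default_tables()) {
  total <- tables$water_mass
  for (ch in oracle_chars(seq)) total <- total + tables$residue_mass[[ch]]
  total
}

oracle_atoms <- function(seq, tables = default_tables()) {
  acc <- c(C = 0, H = 2, N = 0, O = 1, S = 0)
  for (ch in oracle_chars(seq)) acc <- acc + tables$residue_atoms[ch, ]
  acc
}

oracle_gravy <- function(seq, tables = default_tables()) {
  s <- 0
  chars <- oracle_chars(seq)
  for (ch in chars) s <- s + tables$kd[[ch]]
  s / length(chars)
}

oracle_aliphatic <- function(seq, tables = default_tables()) {
  n_a <- 0; n_v <- 0; n_i <- 0; n_l <- 0; n <- 0
  for (ch in oracle_chars(seq)) {
    n <- n + 1
    if (ch == "A") n_a <- n_a + 1
    if (ch == "V") n_v <- n_v + 1
    if (ch == "I") n_i <- n_i + 1
    if (ch == "L") n_l <- n_l + 1
  }
  a <- tables$aliphatic[["a"]]; b <- tables$aliphatic[["b"]]
  100 * n_a / n + a * (100 * n_v / n) + b * (100 * n_i / n + 100 * n_l / n)
}

# Brute-force pI: finest-grid scan for the pH where net charge changes sign.
oracle_pi_scan <- function(seq, step = 0.001, tables = default_tables()) {
  grid <- seq.int(0, 14 / step) * step
  q <- net_charge(seq, grid, tables)
  i <- which(q <= 0)[1]
  (grid[i - 1] + grid[i]) / 2
}

expect_valid_png <- function(path) {
  expect_true(file.exists(path))
  magic <- readBin(path, "raw", 8)
  expect_identical(magic, as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)))
}

file_bytes <- function(path) readBin(path, "raw", file.info(path)$size)
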