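tab <- default_tables()

test_that("residue_composition counts and normalizes", {
  p <- residue_composition("AAG")
  expect_identical(p$counts[["A"]], 2L)
  expect_identical(p$counts[["G"]], 1L)
  expect_equal(p$mole_percent[["A"]], 200 / 3)
  expect_identical(sum(p$counts), p$length)

  uniform <- residue_composition("ACDEFGHIKLMNPQRSTVWY")
  expect_true(all(uniform$counts == 1L))
  expect_true(all(uniform$mole_percent == 5))

  amb <- residue_composition("AXA")
  expect_identical(amb$counts[["X"]], 1L)
  expect_false("B" %in% names(amb$counts))
})

test_that("molecular weight matches the elemental oracle and flags ambiguity", {
  aw <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, S = 32.06)
  gly_elemental <- sum(c(C = 2, H = 5, N = 1, O = 2, S = 0) * aw)
  expect_lt(abs(as.numeric(molecular_weight("G")) - gly_elemental), 0.01)

  gg <- as.numeric(molecular_weight("GG"))
  expect_equal(gg, 2 * as.numeric(molecular_weight("G")) - tab$water_mass,
               tolerance = 1e-12)

  expect_error(molecular_weight("AXA"), class = "protprops_error_mass_undefined")

  # B averages Asn/Asp; Z averages Gln/Glu; both flag approximate
  b <- molecular_weight("B")
  expect_equal(as.numeric(b),
               (tab$residue_mass[["N"]] + tab$residue_mass[["D"]]) / 2 + tab$water_mass)
  expect_true(attr(b, "approximate"))
  expect_false(attr(molecular_weight("AA"), "approximate"))
})

test_that("mass additivity holds over seeded random unambiguous pairs", {
  for (i in 1:100) {
    s1 <- random_sequence(sample(1:60, 1), seed = 2 * i)
    s2 <- random_sequence(sample(1:60, 1), seed = 2 * i + 1)
    cat_seq <- parse_sequence(paste0(s1$residues, s2$residues))
    lhs <- as.numeric(molecular_weight(cat_seq, tab))
    rhs <- as.numeric(molecular_weight(s1, tab)) +
      as.numeric(molecular_weight(s2, tab)) - tab$water_mass
    expect_lt(abs(lhs - rhs), 1e-9)
  }
})

test_that("net charge follows the Henderson-Hasselbalch model", {
  # a single group evaluated at its own pK contributes exactly 1/2
  expect_equal(1 / (1 + 10^0), 0.5)
  # poly-Ala limits: +1 at pH 0, -1 at pH 14 (termini only)
  expect_lt(abs(net_charge("AAAA", 0) - 1), 1e-3)
  expect_lt(abs(net_charge("AAAA", 14) + 1), 1e-3)
  # poly-Asp at pH 14: 4 side chains + C-terminus fully deprotonated
  expect_lt(abs(net_charge("DDDD", 14) + 5), 1e-3)
  expect_error(net_charge("AAAA", -1), class = "protprops_error_invalid_input")
})

test_that("net charge is strictly decreasing in pH for any sequence", {
  grid <- seq(0, 14, by = 0.01)
  for (seq in c(worked_example_set(),
                list(random_sequence(80, seed = 11)))) {
    q <- net_charge(seq, grid, tab)
    expect_true(all(diff(q) < 0),
                label = sprintf("monotone charge for %s", seq$seq_id))
  }
})

test_that("theoretical pI zeroes the net charge and matches closed forms", {
  for (seq in worked_example_set()) {
    pi <- theoretical_pi(seq, tab)
    expect_lte(abs(net_charge(seq, pi, tab)), 1e-4)
    expect_gt(pi, 0); expect_lt(pi, 14)
  }
  # two-group system: root exactly at the midpoint of the terminal pKs
  expect_lt(abs(theoretical_pi("AAAA") - (tab$pk[["Nterm"]] + tab$pk[["Cterm"]]) / 2),
            0.01)
  # basic/acidic homopolymers, verified against the brute-force charge scan
  k10 <- theoretical_pi("KKKKKKKKKK")
  d10 <- theoretical_pi("DDDDDDDDDD")
  expect_gt(k10, 9.5)
  expect_lt(d10, 4.5)
  expect_lt(abs(k10 - oracle_pi_scan(parse_sequence("KKKKKKKKKK"))), 0.001)
  expect_lt(abs(d10 - oracle_pi_scan(parse_sequence("DDDDDDDDDD"))), 0.001)
})

test_that("atomic composition matches known formulas and rejects ambiguity", {
  g <- atomic_composition("G")
  expect_equal(g$atoms, c(C = 2, H = 5, N = 1, O = 2, S = 0))
  expect_identical(g$formula, "C2H5NO2")
  expect_identical(g$total_atoms, 10)

  cys <- atomic_composition("C")
  expect_equal(cys$atoms[["S"]], 1)
  expect_identical(cys$formula, "C3H7NO2S")

  expect_error(atomic_composition("AZA"), class = "protprops_error_ambiguous")
  expect_error(atomic_composition("AXA"), class = "protprops_error_ambiguous")
  expect_error(atomic_composition("ABA"), class = "protprops_error_ambiguous")
})

test_that("atomic composition is additive minus one water", {
  for (i in 1:50) {
    s1 <- random_sequence(sample(1:40, 1), seed = 300 + 2 * i)
    s2 <- random_sequence(sample(1:40, 1), seed = 301 + 2 * i)
    cat_seq <- parse_sequence(paste0(s1$residues, s2$residues))
    lhs <- atomic_composition(cat_seq, tab)$atoms
    rhs <- atomic_composition(s1, tab)$atoms + atomic_composition(s2, tab)$atoms -
      c(C = 0, H = 2, N = 0, O = 1, S = 0)
    expect_identical(lhs, rhs)
  }
})

test_that("charged residue counts follow the Asp+Glu / Arg+Lys definition", {
  expect_identical(charged_residue_counts("DEKR"),
                   list(n_negative = 2L, n_positive = 2L))
  expect_identical(charged_residue_counts("HHHH"),
                   list(n_negative = 0L, n_positive = 0L))
  expect_identical(charged_residue_counts("AAAA"),
                   list(n_negative = 0L, n_positive = 0L))
})

test_that("aliphatic index reproduces the closed-form values", {
  expect_equal(aliphatic_index("AAAA"), 100)
  expect_equal(aliphatic_index("VVVV"), 290)
  expect_equal(aliphatic_index("AVIL"), 292.5)
  expect_equal(aliphatic_index("GGGG"), 0)
  # accepts a profile directly
  expect_equal(aliphatic_index(residue_composition("AVIL")), 292.5)
})

test_that("GRAVY reproduces scale values and rejects ambiguity", {
  expect_equal(gravy("IIII"), 4.5)
  expect_equal(gravy("RRRR"), -4.5)
  expect_equal(gravy("IR"), 0)
  expect_error(gravy("AXA"), class = "protprops_error_ambiguous")
})

test_that("properties are invariant under permutation of the residues", {
  s <- random_sequence(60, seed = 99)
  chars <- strsplit(s$residues, "")[[1]]
  for (i in 1:10) {
    perm <- parse_sequence(paste(sample(chars), collapse = ""))
    expect_equal(as.numeric(molecular_weight(perm, tab)),
                 as.numeric(molecular_weight(s, tab)))
    expect_identical(atomic_composition(perm, tab)$atoms,
                     atomic_composition(s, tab)$atoms)
    expect_equal(aliphatic_index(perm, tab), aliphatic_index(s, tab))
    expect_equal(gravy(perm, tab), gravy(s, tab))
    expect_equal(theoretical_pi(perm, tab), theoretical_pi(s, tab))
  }
})

test_that("compute_report assembles full and partial reports", {
  full <- compute_report("ACDEFGHIKLMNPQRSTVWY")
  expect_false(full$ambiguous)
  expect_length(full$unavailable, 0)
  expect_identical(full$n_residues, 20L)
  expect_false(is.null(full$atomic))

  partial <- compute_report("AXA")
  expect_true(partial$ambiguous)
  expect_identical(partial$n_residues, 3L)
  expect_true(all(c("molecular_weight", "atomic", "gravy") %in%
                    names(partial$unavailable)))
  expect_true(is.na(partial$molecular_weight))
  expect_null(partial$atomic)
  expect_false(is.na(partial$theoretical_pi))

  # B/Z: mass available but approximate; atomic and gravy unavailable
  bz <- compute_report("ABZA")
  expect_false(is.na(bz$molecular_weight))
  expect_true(bz$mw_approximate)
  expect_null(bz$atomic)
  expect_true(bz$ambiguous)
})
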