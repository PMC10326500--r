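---
title: "Computing and comparing protein physicochemical properties"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing and comparing protein physicochemical properties}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protprops)
```

The primary sequence of a protein already fixes a family of properties
that correlate with its behaviour in solution and its stability: size and
mass, charge as a function of pH, elemental makeup, the volume fraction of
aliphatic side chains, and average hydropathy. `protprops` computes this
classical property set for one sequence and compares two sequences
head-to-head, the workflow a bench scientist would otherwise run through a
web form one protein at a time.

## The property models

**Molecular weight.** A chain of residues has mass
$\mathrm{MW} = \sum_i m_i + m_{\mathrm{H_2O}}$, where $m_i$ are *residue*
masses — free amino acid minus one water, since each peptide bond releases
a water — and one water is added back for the free termini. The packaged
masses are the average isotopic residue masses used across the ExPASy
family of tools (`inst/extdata/constants.yaml`); monoisotopic masses and
post-translational modifications are out of scope.

**Net charge and theoretical pI.** Each ionizable group $g$ (the two
termini and the Asp, Glu, Cys, Tyr, His, Lys, Arg side chains) carries a
Henderson–Hasselbalch partial charge:

$$Z(\mathrm{pH}) = \sum_{g \in \mathrm{basic}} \frac{n_g}{1 + 10^{\mathrm{pH} - pK_g}}
 - \sum_{g \in \mathrm{acidic}} \frac{n_g}{1 + 10^{pK_g - \mathrm{pH}}}$$

with $n_g$ the number of occurrences (termini count once each). $Z$ is
continuous and strictly decreasing in pH, positive at pH 0 and negative at
pH 14 (the termini guarantee both limits), so it has exactly one root: the
theoretical pI. The pK set is the Bjellqvist-style set derived from
polypeptide migration in immobilized pH gradients (C-terminus 3.55,
Asp 4.05, Glu 4.45, His 5.98, N-terminus 7.50, Cys 9.00, Tyr 10.00,
Lys 10.00, Arg 12.00). A single N-terminal pK is used for all residues;
residue-specific N-terminal pKs are a known refinement that a swapped
constants file can provide. Cysteines are treated as reduced free thiols —
no disulfide handling.

**Aliphatic index.** With $X(r)$ the mole percent of residue $r$,

$$\mathrm{AI} = X(\mathrm{Ala}) + a\,X(\mathrm{Val}) + b\,[X(\mathrm{Ile}) + X(\mathrm{Leu})],
\quad a = 2.9,\; b = 3.9,$$

the coefficients being side-chain volumes relative to alanine. AI ranges
over $[0, 390]$ and correlates positively with the thermostability of
globular proteins; it decides the thermostability verdict in comparisons.

**GRAVY.** The grand average of hydropathicity is the mean Kyte–Doolittle
hydropathy over all residues, bounded by the scale's extremes
$[-4.5, 4.5]$ (Arg to Ile); positive values indicate hydrophobic proteins.
It decides the hydrophobicity verdict.

```{r closed-forms}
aliphatic_index("AVIL")   # 25 + 2.9*25 + 3.9*50
gravy("IR")               # (4.5 - 4.5)/2
theoretical_pi("AAAA")    # midpoint of the terminal pKs
```

## Ambiguity codes

Sequences may contain B (Asn or Asp), Z (Gln or Glu) and X (unspecified).
These make some properties undefined, and the package is explicit about
which:

- **Composition, length, charged-residue counts**: always computed; B/X/Z
  get their own composition rows.
- **Molecular weight**: B and Z take the arithmetic mean of their two
  candidate masses and the result is flagged approximate (the candidates
  differ by under 1 Da, so the error is tiny); X has no defensible mass and
  the property is unavailable.
- **Atomic composition and GRAVY**: unavailable for any B/X/Z — averaging
  elemental formulas would fabricate a molecule, and silently dropping
  residues from a mean would change the denominator invisibly.
- **Net charge and pI**: still computed, with ambiguous residues
  contributing no side-chain charge. For B this understates acidity when
  the residue is actually Asp; the alternative — refusing to report a pI
  for any sequence with one ambiguous position — helps nobody, and the
  report's `ambiguous` flag marks the caveat.

`compute_report()` therefore never fails on a valid sequence: unavailable
fields carry a reason, and the text report prints an explicit
`unavailable:` line rather than omitting them. Comparisons require GRAVY
on both sides and refuse ambiguous inputs; the command-line `compare` then
still writes the per-protein artifacts and the composition overlay
(composition is always defined) and skips only the verdict panel, with a
warning.

Input validation is deliberately stricter than lenient web forms: after
stripping whitespace and digits and uppercasing, any character outside the
23-letter alphabet — including `*` — is rejected with its position.
Silently accepting a mis-pasted sequence corrupts every downstream number.

## Numerical choices

- **pI solver**: bisection on $[0, 14]$, terminating at $|Z| \le 10^{-4}$
  or interval width $\le 10^{-4}$. Bisection is chosen over faster
  root-finders because monotonicity makes its convergence unconditional;
  at ~45 charge evaluations per sequence the cost is irrelevant.
- **Precision**: mole percents are kept at full precision internally;
  rounding (1 decimal in composition tables and pie-chart labels, 2
  decimals for MW/pI/AI, 3 for GRAVY) happens only at the rendering layer.
  A 20-row table of 1-decimal percents can drift from 100.0 by up to 0.05
  per row after rounding; the 5-wedge atomic pie stays within ±0.25.
- **Ties**: comparison verdicts use an absolute tolerance (default
  $10^{-9}$) so a protein compared with itself yields `=` rather than an
  arbitrary strict order.
- **Formula rendering**: elements in C, H, N, O, S order, count suffix
  omitted when 1, zero-count elements omitted (`C2H5NO2` for glycine).
- **Determinism**: chart functions return their computed data (bar
  heights, wedge percentages, series) for numeric assertion, and with
  fixed raster parameters the cairo PNG device renders byte-identically,
  so whole output directories can be compared between runs.

## The synthetic-sequence generator

`random_sequence()` draws residues i.i.d. from a configurable weight
vector (uniform over the 20 canonical residues by default), optionally
replacing positions with B/X/Z at a given rate, under an explicit seed
that never disturbs the caller's random stream. It emulates only what the
property computations care about — residue multisets of controlled length
and ambiguity content — and none of what real proteins have: no
organism-specific residue frequencies, no compositional autocorrelation,
no domain structure. That is sufficient here because every property in
the package is a pure function of the residue multiset (the permutation
invariance the tests check), so passing on uniform random sequences
transfers directly to real sequences; what it does not probe is the
*typical range* of real-protein values. Property tests run on sequences of
length 1–500 (about 1,000 sequences for the normalization and bound
checks, 200 for oracle-equivalence), sizes at which every check completes
in seconds while still covering one-residue edge cases and chains well
past the display-wrapping width.

## Limitations

- Average (not monoisotopic) masses; no modifications, no disulfides.
- One fixed pK set and hydropathy scale; alternates require swapping the
  constants file, which `validate_tables()` will re-check.
- Comparison is defined for exactly two proteins, mirroring the two-slot
  workflow it reimplements; the TSV writer already accepts arbitrary lists.
- The pI of heavily His/Cys-rich peptides is as good as the single-pK
  model: no residue-specific terminal pKs, no charge suppression effects.
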