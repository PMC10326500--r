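# protprops

Physicochemical properties and head-to-head comparison of protein
amino-acid sequences, for anyone who wants ProtParam-style numbers — and a
two-protein comparison — reproducibly from a library or the command line
rather than a web form: protein biochemists screening constructs,
bioinformaticians annotating sequence sets, teachers building exercises.

From a one-letter-code sequence or FASTA record, `protprops` computes:

- **Length** and **amino-acid composition** (counts and mole percent,
  X(r) = 100 · n(r)/N);
- **Average molecular weight**: MW = Σᵢ mᵢ + m(H₂O), the sum of average
  isotopic residue masses plus one water;
- **Theoretical pI**: the root of the Henderson–Hasselbalch net charge
  Z(pH) = Σ_basic n_g /(1+10^(pH−pK_g)) − Σ_acidic n_g /(1+10^(pK_g−pH)),
  found by bisection on [0, 14] (Z is strictly decreasing, so the root is
  unique);
- **Atomic composition**: C/H/N/O/S counts, molecular formula, total atoms;
- **Charged residues**: Asp+Glu (negative) and Arg+Lys (positive);
- **Aliphatic index**, a thermostability correlate:
  AI = X(Ala) + 2.9·X(Val) + 3.9·[X(Ile) + X(Leu)];
- **GRAVY**: mean Kyte–Doolittle hydropathy, positive = hydrophobic.

Two proteins can be compared for thermostability (AI) and hydrophobicity
(GRAVY), with `>`/`<`/`=` verdicts, an amino-acid composition overlay plot
and a verdict panel. The ambiguity codes B, X and Z are accepted with
explicit partial-report semantics: composition and pI are always computed,
atomic composition and GRAVY (and MW when X is present) are reported as
unavailable with a reason.

## Worked example

```r
library(protprops)
rep <- compute_report("AAG")
print(rep)
```

```
=== Protein-1 ===
Sequence: (unnamed)
  AAG
Number of amino acids: 3
Molecular weight (Da): 217.22
Theoretical pI: 5.52
Amino acid composition:
  Ala     2   66.7
  Arg     0    0.0
  ...
Total number of negatively charged residues (Asp + Glu): 0
Total number of positively charged residues (Arg + Lys): 0
Atomic composition:
  Carbon   C      8
  Hydrogen H     15
  Nitrogen N      3
  Oxygen   O      4
  Sulfur   S      0
Formula: C8H15N3O4
Total number of atoms: 30
Aliphatic index: 66.67
Grand average of hydropathicity (GRAVY): 1.067
```

Two alanines and a glycine: MW is the three residue masses plus one water
(217.22 Da); the pI 5.52 is the midpoint of the terminal pKs (7.50 and
3.55) since no side chain ionizes; AI is 66.67 because X(Ala) = 66.7 and no
Val/Ile/Leu are present; GRAVY 1.067 = (1.8 + 1.8 − 0.4)/3.

Comparison, from R or the shell:

```r
run_compare("AVIL", "GGGG", out_dir = "out", formats = c("txt", "tsv", "png"))
```

```sh
exec/protprops compare p1.fasta p2.fasta --out out --formats txt,tsv,png
```

writes the combined text report, a two-row TSV, per-protein composition
bar and atomic pie charts, the composition overlay and the verdict panel
(here `Protein-1 > Protein-2` on both rows: AI 292.5 vs 0, GRAVY 3.575 vs
−0.400).

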