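# Numeric tables for protein physicochemical property calculation.
#
# residues: one entry per canonical amino acid (one-letter key), giving
#   name3  - three-letter abbreviation
#   mass   - average isotopic residue mass in Da (amino acid minus one water),
#            the table used by the ExPASy family of tools
#   atoms  - elemental counts C/H/N/O/S of the residue (minus one water)
#   kd     - Kyte & Doolittle (1982) hydropathy value
# water_mass: average isotopic mass of one H2O, added once per chain.
# pk: pK values of the ionizable groups (Bjellqvist-style set) with their
#   charge sign class; side-chain groups are keyed by one-letter residue code.
# aliphatic_coefficients: relative side-chain volumes for the aliphatic
#   index (a = Val, b = Leu/Ile, both relative to Ala).
water_mass: 18.01524
aliphatic_coefficients:
  a: 2.9
  b: 3.9
pk:
  Nterm: {value: 7.50, sign: basic}
  Cterm: {value: 3.55, sign: acidic}
  'D':     {value: 4.05, sign: acidic}
  'E':     {value: 4.45, sign: acidic}
  'C':     {value: 9.00, sign: acidic}
  'Y':     {value: 10.00, sign: acidic}
  'H':     {value: 5.98, sign: basic}
  'K':     {value: 10.00, sign: basic}
  'R':     {value: 12.00, sign: basic}
residues:
  'A': {name3: Ala, mass: 71.0788,  atoms: {'C': 3,  'H': 5,  'N': 1, 'O': 1, 'S': 0}, kd: 1.8}
  'R': {name3: Arg, mass: 156.1875, atoms: {'C': 6,  'H': 12, 'N': 4, 'O': 1, 'S': 0}, kd: -4.5}
  'N': {name3: Asn, mass: 114.1038, atoms: {'C': 4,  'H': 6,  'N': 2, 'O': 2, 'S': 0}, kd: -3.5}
  'D': {name3: Asp, mass: 115.0886, atoms: {'C': 4,  'H': 5,  'N': 1, 'O': 3, 'S': 0}, kd: -3.5}
  'C': {name3: Cys, mass: 103.1388, atoms: {'C': 3,  'H': 5,  'N': 1, 'O': 1, 'S': 1}, kd: 2.5}
  'Q': {name3: Gln, mass: 128.1307, atoms: {'C': 5,  'H': 8,  'N': 2, 'O': 2, 'S': 0}, kd: -3.5}
  'E': {name3: Glu, mass: 129.1155, atoms: {'C': 5,  'H': 7,  'N': 1, 'O': 3, 'S': 0}, kd: -3.5}
  'G': {name3: Gly, mass: 57.0519,  atoms: {'C': 2,  'H': 3,  'N': 1, 'O': 1, 'S': 0}, kd: -0.4}
  'H': {name3: His, mass: 137.1411, atoms: {'C': 6,  'H': 7,  'N': 3, 'O': 1, 'S': 0}, kd: -3.2}
  'I': {name3: Ile, mass: 113.1594, atoms: {'C': 6,  'H': 11, 'N': 1, 'O': 1, 'S': 0}, kd: 4.5}
  'L': {name3: Leu, mass: 113.1594, atoms: {'C': 6,  'H': 11, 'N': 1, 'O': 1, 'S': 0}, kd: 3.8}
  'K': {name3: Lys, mass: 128.1741, atoms: {'C': 6,  'H': 12, 'N': 2, 'O': 1, 'S': 0}, kd: -3.9}
  'M': {name3: Met, mass: 131.1926, atoms: {'C': 5,  'H': 9,  'N': 1, 'O': 1, 'S': 1}, kd: 1.9}
  'F': {name3: Phe, mass: 147.1766, atoms: {'C': 9,  'H': 9,  'N': 1, 'O': 1, 'S': 0}, kd: 2.8}
  'P': {name3: Pro, mass: 97.1167,  atoms: {'C': 5,  'H': 7,  'N': 1, 'O': 1, 'S': 0}, kd: -1.6}
  'S': {name3: Ser, mass: 87.0782,  atoms: {'C': 3,  'H': 5,  'N': 1, 'O': 2, 'S': 0}, kd: -0.8}
  'T': {name3: Thr, mass: 101.1051, atoms: {'C': 4,  'H': 7,  'N': 1, 'O': 2, 'S': 0}, kd: -0.7}
  'W': {name3: Trp, mass: 186.2132, atoms: {'C': 11, 'H': 10, 'N': 2, 'O': 1, 'S': 0}, kd: -0.9}
  'Y': {name3: Tyr, mass: 163.1760, atoms: {'C': 9,  'H': 9,  'N': 1, 'O': 2, 'S': 0}, kd: -1.3}
  'V': {name3: Val, mass: 99.1326,  atoms: {'C': 5,  'H': 9,  'N': 1, 'O': 1, 'S': 0}, kd: 4.2}
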