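## Physico-chemical constants for protein characterization, collected in
## one place so they can be tuned for parity with other calculators.

## Average (isotope-abundance-weighted) residue masses in Da, i.e. amino
## acid mass minus one water; a peptide's mass is the residue sum plus one
## water.
AA_RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)

WATER_MASS <- 18.01524

## pKa values for the ionizable groups used by the net-charge model
## (EMBOSS-style set). Positive groups: N-terminus, K, R, H; negative:
## C-terminus, D, E, C, Y.
PKA <- c(
  nterm = 8.6, cterm = 3.6,
  K = 10.8, R = 12.5, H = 6.5,
  D = 3.9, E = 4.1, C = 8.5, Y = 10.1
)
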