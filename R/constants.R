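# Monoisotopic masses (Da). Exact values are required: nominal "+80/-18"
# phospho shifts would fall outside the 0.05 Th matching tolerance.

PROTON_MASS <- 1.00727646677
H2O_MASS <- 18.0105646837
NH3_MASS <- 17.02654910101
CO_MASS <- 27.99491461956
HPO3_MASS <- 79.96633052075  # intact phospho shift on a fragment
H3PO4_MASS <- 97.97689520445 # phosphoric acid neutral loss

# Standard residue monoisotopic masses for the 20 amino acids.
RESIDUE_MASS <- c(
  G = 57.02146373, A = 71.03711379, S = 87.03202841, P = 97.05276385,
  V = 99.06841391, T = 101.04767847, C = 103.00918448, L = 113.08406398,
  I = 113.08406398, N = 114.04292744, D = 115.02694302, Q = 128.05857750,
  K = 128.09496302, E = 129.04259309, M = 131.04048509, H = 137.05891186,
  F = 147.06841391, R = 156.10111102, Y = 163.06332853, W = 186.07931295
)

# Residues whose presence in a fragment licenses ammonia / water neutral loss.
NH3_LOSS_RESIDUES <- c("R", "K", "N", "Q")
H2O_LOSS_RESIDUES <- c("S", "T", "E", "D")

# Acquisition m/z range of the emulated instrument; also the binning range.
MZ_RANGE_DEFAULT <- c(100, 1600)

# Fragment-ion matching tolerance (Th).
FRAGMENT_TOL_DEFAULT <- 0.05
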