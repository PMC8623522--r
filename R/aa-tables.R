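# Published amino-acid constant tables used by the feature module.
# Sources: ProtParam average residue masses; ProtParam pKa set;
# Guruprasad et al. (1990) dipeptide instability weights (DIWV);
# Kyte & Doolittle (1982) hydropathy; Vihinen et al. (1994) flexibility;
# Grantham (1974) polarity; Zamyatnin (1972) volume; Chou & Fasman (1978)
# secondary-structure propensities.

AA_STANDARD <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S","T","V","W","Y")

WATER_MASS <- 18.0153

AA_RESIDUE_MASS <- c(A = 71.0779, C = 103.1429, D = 115.0874, E = 129.114, F = 147.1738, G = 57.0513, H = 137.1393, I = 113.1576, K = 128.1723, L = 113.1576, M = 131.196, N = 114.1026, P = 97.1152, Q = 128.1292, R = 156.1857, S = 87.0773, T = 101.1039, V = 99.131, W = 186.2099, Y = 163.1732)

# side-chain / terminal pKa values (ProtParam convention)
PKA_POSITIVE <- c(Nterm = 7.5, K = 10.0, R = 12.0, H = 5.98)
PKA_NEGATIVE <- c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0)

AA_KD_HYDROPATHY <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2, I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)

AA_FLEXIBILITY <- c(A = 0.984, C = 0.906, D = 1.068, E = 1.094, F = 0.915, G = 1.031, H = 0.95, I = 0.927, K = 1.102, L = 0.935, M = 0.952, N = 1.048, P = 1.049, Q = 1.037, R = 1.008, S = 1.046, T = 0.997, V = 0.931, W = 0.904, Y = 0.929)

# DIWV[i, j]: instability weight of dipeptide i-j (row = first residue)
AA_DIWV <- matrix(c(
  1, 44.94, -7.49, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 1,
  1, 1, 20.26, 1, 1, 1, 33.6, 1, 1, 20.26, 33.6, 1, 20.26, -6.54, 1, 1, 33.6, -6.54, 24.68, 1,
  1, 1, 1, 1, -6.54, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, -6.54, 20.26, -14.03, 1, 1, 1,
  1, 44.94, 20.26, 33.6, 1, 1, -6.54, 20.26, 1, 1, 1, 1, 20.26, 20.26, 1, 20.26, 1, 1, -14.03, 1,
  1, 1, 13.34, 1, 1, 1, 1, 1, -14.03, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 33.601,
  -7.49, 1, 1, -6.54, 1, 13.34, 1, -7.49, -7.49, 1, 1, -7.49, 1, 1, 1, 1, -7.49, 1, 13.34, -7.49,
  1, 1, 1, 1, -9.37, -9.37, 1, 44.94, 24.68, 1, 1, 24.68, -1.88, 1, 1, 1, -6.54, 1, -1.88, 44.94,
  1, 1, 1, 44.94, 1, 1, 13.34, 1, -7.49, 20.26, 1, 1, -1.88, 1, 1, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, -7.49, 1, -7.49, 1, -7.49, 33.6, 1, -6.54, 24.64, 33.6, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, 1, 1, 1, -7.49, 1, 1, 1, 20.26, 33.6, 20.26, 1, 1, 1, 24.68, 1,
  13.34, 1, 1, 1, 1, 1, 58.28, 1, 1, 1, -1.88, 1, 44.94, -6.54, -6.54, 44.94, -1.88, 1, 1, 24.68,
  1, -1.88, 1, 1, -14.03, -14.03, 1, 44.94, 24.68, 1, 1, 1, -1.88, -6.54, 1, 1, -7.49, 1, -9.37, 1,
  20.26, -6.54, -6.54, 18.38, 20.26, 1, 1, 1, 1, 1, -6.54, 1, 20.26, 20.26, -6.54, 20.26, 1, 20.26, -1.88, 1,
  1, -6.54, 20.26, 20.26, -6.54, 1, 1, 1, 1, 1, 1, 1, 20.26, 20.26, 1, 44.94, 1, -6.54, 1, -6.54,
  1, 1, 1, 1, 1, -7.49, 20.26, 1, 1, 1, 1, 13.34, 20.26, 20.26, 58.28, 44.94, 1, 1, 58.28, -6.54,
  1, 33.6, 1, 20.26, 1, 1, 1, 1, 1, 1, 1, 1, 44.94, 20.26, 20.26, 20.26, 1, 1, 1, 1,
  1, 1, 1, 20.26, 13.34, -7.49, 1, 1, 1, 1, 1, -14.03, 1, -6.54, 1, 1, 1, 1, -14.03, 1,
  1, 1, -14.03, 1, 1, -7.49, 1, 1, -1.88, 1, 1, 1, 20.26, 1, 1, 1, -7.49, 1, 1, -6.54,
  -14.03, 1, 1, 1, 1, -9.37, 24.68, 1, 1, 13.34, 24.68, 13.34, 1, 1, 1, 1, -14.03, -7.49, 1, 1,
  24.68, 1, 24.68, -6.54, 1, -7.49, 13.34, 1, 1, 1, 44.94, 1, 13.34, 1, -15.91, 1, -7.49, 1, -9.37, 13.34
), nrow = 20, byrow = TRUE, dimnames = list(AA_STANDARD, AA_STANDARD))

AA_GRANTHAM_POLARITY <- c(
  A = 8.1, C = 5.5, D = 13.0, E = 12.3, F = 5.2, G = 9.0, H = 10.4, I = 5.2,
  K = 11.3, L = 4.9, M = 5.7, N = 11.6, P = 8.0, Q = 10.5, R = 10.5, S = 9.2,
  T = 8.6, V = 5.9, W = 5.4, Y = 6.2)

AA_VOLUME <- c(
  A = 88.6, C = 108.5, D = 111.1, E = 138.4, F = 189.9, G = 60.1, H = 153.2,
  I = 166.7, K = 168.6, L = 166.7, M = 162.9, N = 114.1, P = 112.7, Q = 143.8,
  R = 173.4, S = 89.0, T = 116.1, V = 140.0, W = 227.8, Y = 193.6)

# unit net charge at neutral pH; H gets a small positive weight
AA_CHARGE <- c(
  A = 0, C = 0, D = -1, E = -1, F = 0, G = 0, H = 0.1, I = 0, K = 1, L = 0,
  M = 0, N = 0, P = 0, Q = 0, R = 1, S = 0, T = 0, V = 0, W = 0, Y = 0)

AA_CF_HELIX <- c(
  A = 1.42, C = 0.70, D = 1.01, E = 1.51, F = 1.13, G = 0.57, H = 1.00,
  I = 1.08, K = 1.16, L = 1.21, M = 1.45, N = 0.67, P = 0.57, Q = 1.11,
  R = 0.98, S = 0.77, T = 0.83, V = 1.06, W = 1.08, Y = 0.69)

AA_CF_SHEET <- c(
  A = 0.83, C = 1.19, D = 0.54, E = 0.37, F = 1.38, G = 0.75, H = 0.87,
  I = 1.60, K = 0.74, L = 1.30, M = 1.05, N = 0.89, P = 0.55, Q = 1.10,
  R = 0.93, S = 0.75, T = 1.19, V = 1.70, W = 1.37, Y = 1.47)

AA_CF_TURN <- c(
  A = 0.66, C = 1.19, D = 1.46, E = 0.74, F = 0.60, G = 1.56, H = 0.95,
  I = 0.47, K = 1.01, L = 0.59, M = 0.60, N = 1.56, P = 1.52, Q = 0.98,
  R = 0.95, S = 1.43, T = 0.96, V = 0.50, W = 0.96, Y = 1.14)

AA_AROMATIC <- c(
  A = 0, C = 0, D = 0, E = 0, F = 1, G = 0, H = 0.5, I = 0, K = 0, L = 0,
  M = 0, N = 0, P = 0, Q = 0, R = 0, S = 0, T = 0, V = 0, W = 1, Y = 1)

# the nine AAIndex-style scale channels of the default feature schema
AA_SCALE_SET <- function() {
  list(
    hydropathy  = AA_KD_HYDROPATHY,
    polarity    = AA_GRANTHAM_POLARITY,
    volume      = AA_VOLUME,
    flexibility = AA_FLEXIBILITY,
    charge      = AA_CHARGE,
    helix       = AA_CF_HELIX,
    sheet       = AA_CF_SHEET,
    turn        = AA_CF_TURN,
    aromaticity = AA_AROMATIC)
}

# compositional alphabets used by the synthetic generator
AA_DISORDER_PROMOTING <- c("P", "E", "S", "Q", "K", "G")
AA_ORDER_PROMOTING    <- c("C", "W", "F", "I", "L", "V", "Y")
AA_TM_HYDROPHOBIC     <- c("A", "F", "G", "I", "L", "M", "V", "W")
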