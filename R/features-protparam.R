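# ProtParam-style peptide descriptors: molecular weight, isoelectric
# point, instability index. Computed per sequence window; a vectorized
# per-position track is provided for feature extraction.

#' ProtParam descriptors of a peptide window
#'
#' Molecular weight (average isotopic residue masses plus one water),
#' isoelectric point (bisection root of the Henderson-Hasselbalch net
#' charge with the ProtParam pKa set, free termini), and the
#' Guruprasad instability index `(10/len) * sum DIWV(i, i+1)`.
#' Non-standard symbols (padding, `X`) are skipped.
#'
#' @param window Amino-acid string (the peptide).
#' @return Named numeric vector `c(mw, pi, instability)` (Da, pH units,
#'   dimensionless).
#' @export
protparam_features <- function(window) {
  aa <- strsplit(toupper(window), "")[[1]]
  aa <- aa[aa %in% AA_STANDARD]
  if (length(aa) == 0) stop("empty effective window")
  mw <- sum(AA_RESIDUE_MASS[aa]) + WATER_MASS
  pi <- isoelectric_point(aa)
  inst <- if (length(aa) >= 2) {
    (10 / length(aa)) *
      sum(AA_DIWV[cbind(aa[-length(aa)], aa[-1])])
  } else 0
  c(mw = mw, pi = pi, instability = inst)
}

# net charge of a peptide at a given pH (vectorized over peptides when
# the residue counts are given as a matrix with one row per peptide)
net_charge <- function(counts, pH) {
  chg <- 1 / (1 + 10^(pH - PKA_POSITIVE["Nterm"]))
  for (a in c("K", "R", "H"))
    chg <- chg + counts[, a] / (1 + 10^(pH - PKA_POSITIVE[a]))
  chg <- chg - 1 / (1 + 10^(PKA_NEGATIVE["Cterm"] - pH))
  for (a in c("D", "E", "C", "Y"))
    chg <- chg - counts[, a] / (1 + 10^(PKA_NEGATIVE[a] - pH))
  chg
}

aa_count_matrix <- function(aa_list) {
  m <- matrix(0L, nrow = length(aa_list), ncol = 20,
              dimnames = list(NULL, AA_STANDARD))
  for (i in seq_along(aa_list)) {
    t <- table(factor(aa_list[[i]], levels = AA_STANDARD))
    m[i, ] <- as.integer(t)
  }
  m
}

# bisection on the monotone-decreasing net-charge curve
pi_bisection <- function(counts, tol = 1e-4, max_iter = 100L) {
  lo <- rep(0, nrow(counts))
  hi <- rep(14, nrow(counts))
  for (k in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    chg <- net_charge(counts, mid)
    up <- chg > 0
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
    if (max(abs(chg)) < tol && max(hi - lo) < tol) break
  }
  (lo + hi) / 2
}

isoelectric_point <- function(aa) {
  counts <- aa_count_matrix(list(aa))
  pi_bisection(counts)
}

#' Per-position ProtParam track
#'
#' For each residue, the three ProtParam descriptors of the +/-`half_width`
#' window centred on it (windows truncated at the sequence ends;
#' non-standard symbols skipped). Vectorized via running window counts.
#'
#' @param sequence Amino-acid string.
#' @param half_width Window half-width in residues.
#' @return `L x 3` matrix with columns `mw`, `pi`, `instability`.
#' @export
protparam_track <- function(sequence, half_width = 5L) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  L <- length(aa)
  std <- aa %in% AA_STANDARD
  starts <- pmax(1L, seq_len(L) - half_width)
  ends <- pmin(L, seq_len(L) + half_width)

  # running counts of each residue type -> per-window count matrix
  ind <- matrix(0L, nrow = L, ncol = 20, dimnames = list(NULL, AA_STANDARD))
  ind[cbind(which(std), match(aa[std], AA_STANDARD))] <- 1L
  cum <- apply(ind, 2, cumsum)
  cum0 <- rbind(0L, cum)
  counts <- cum0[ends + 1L, , drop = FALSE] - cum0[starts, , drop = FALSE]
  nres <- rowSums(counts)
  if (any(nres == 0))
    stop("window with no standard residues at position ",
         which(nres == 0)[1])

  mw <- as.vector(counts %*% AA_RESIDUE_MASS[AA_STANDARD]) + WATER_MASS
  pi <- pi_bisection(counts)

  # windowed sum of dipeptide instability weights over adjacent pairs
  dip <- numeric(max(L - 1L, 0L))
  ok <- std[-L] & std[-1L]
  if (any(ok))
    dip[ok] <- AA_DIWV[cbind(aa[-L][ok], aa[-1L][ok])]
  dcum <- c(0, cumsum(dip))
  pair_end <- pmax(ends - 1L, starts - 1L)
  inst_sum <- dcum[pair_end + 1L] - dcum[starts]
  inst <- ifelse(nres >= 2, (10 / nres) * inst_sum, 0)

  cbind(mw = mw, pi = pi, instability = inst)
}
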