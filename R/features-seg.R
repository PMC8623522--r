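# SEG-style low-complexity detection: windowed Shannon entropy with
# trigger/extension thresholds.

#' Low-complexity mask (SEG-style two-threshold scan)
#'
#' Slides a window of width `W` along the sequence and computes the
#' compositional Shannon entropy K = -sum f_a log2 f_a of each window.
#' Windows with K <= `K_trig` seed low-complexity regions; seeds are
#' extended over adjacent windows while K <= `K_ext`; the mask is TRUE on
#' every residue covered by an accepted window. Defaults are the canonical
#' SEG parameters (12 / 2.2 / 2.5).
#'
#' @param sequence Amino-acid sequence (single string).
#' @param W Window width (>= 1); sequences shorter than `W` are scanned
#'   with a single full-length window.
#' @param K_trig Entropy threshold (bits) that seeds a region.
#' @param K_ext Entropy threshold (bits) up to which seeds extend.
#' @return Logical vector of length `nchar(sequence)`.
#' @export
seg_mask <- function(sequence, W = 12L, K_trig = 2.2, K_ext = 2.5) {
  if (W < 1) stop("window width must be >= 1")
  aa <- strsplit(toupper(sequence), "")[[1]]
  L <- length(aa)
  if (L == 0) stop("empty sequence")
  w <- min(W, L)
  nwin <- L - w + 1L
  K <- window_entropy(aa, w)
  seeds <- which(K <= K_trig)
  mask <- rep(FALSE, L)
  if (length(seeds) == 0) return(mask)
  ok_ext <- K <= K_ext
  keep <- rep(FALSE, nwin)
  for (s in seeds) {
    keep[s] <- TRUE
    i <- s - 1L
    while (i >= 1L && ok_ext[i]) { keep[i] <- TRUE; i <- i - 1L }
    i <- s + 1L
    while (i <= nwin && ok_ext[i]) { keep[i] <- TRUE; i <- i + 1L }
  }
  for (i in which(keep)) mask[i:(i + w - 1L)] <- TRUE
  mask
}

# entropy of each length-w window, by incremental count updates
window_entropy <- function(aa, w) {
  L <- length(aa)
  nwin <- L - w + 1L
  code <- match(aa, unique(aa))
  nsym <- max(code)
  counts <- tabulate(code[1:w], nbins = nsym)
  ent <- function(cnt) {
    f <- cnt[cnt > 0] / sum(cnt)
    -sum(f * log2(f))
  }
  K <- numeric(nwin)
  K[1] <- ent(counts)
  if (nwin > 1) for (i in 2:nwin) {
    counts[code[i - 1L]] <- counts[code[i - 1L]] - 1L
    counts[code[i + w - 2L]] <- counts[code[i + w - 2L]] + 1L
    K[i] <- ent(counts)
  }
  K
}
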