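# Global sequence identity and greedy redundancy clustering.

#' Global pairwise sequence identity
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap opening 10, gap
#' extension 0.5) via [Biostrings::pairwiseAlignment()]; identity is the
#' number of identical aligned positions divided by the alignment length
#' (gaps included).
#'
#' @param a,b Amino-acid sequences (single strings).
#' @return Identity fraction in `[0, 1]`.
#' @export
seq_identity <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = get_blosum62(),
    gapOpening = 10, gapExtension = 0.5)
  aln_len <- nchar(as.character(Biostrings::alignedPattern(pa)))
  Biostrings::nmatch(pa) / aln_len
}

# 3-mer Jaccard similarity; cheap screen before alignment (CD-HIT-style
# word filter). Pairs below the cutoff are assumed non-redundant.
kmer_set <- function(s, k = 3L) {
  n <- nchar(s)
  if (n < k) return(s)
  unique(substring(s, 1:(n - k + 1), k:n))
}

kmer_jaccard <- function(a, b, k = 3L) {
  ka <- kmer_set(a, k); kb <- kmer_set(b, k)
  length(intersect(ka, kb)) / length(union(ka, kb))
}

# inverted 3-mer index: for each query, pool members whose estimated
# Jaccard reaches the cutoff (all pool members when cutoff is 0)
word_filter_candidates <- function(query_seqs, pool_seqs, cutoff,
                                   k = 3L) {
  if (cutoff <= 0)
    return(lapply(query_seqs, function(q) seq_along(pool_seqs)))
  pool_k <- lapply(pool_seqs, kmer_set, k = k)
  pool_sizes <- lengths(pool_k)
  npool <- length(pool_seqs)
  postings <- split(rep(seq_len(npool), pool_sizes), unlist(pool_k))
  lapply(query_seqs, function(q) {
    qk <- kmer_set(q, k)
    hits <- unlist(postings[qk], use.names = FALSE)
    if (is.null(hits) || length(hits) == 0) return(integer(0))
    ov <- tabulate(hits, nbins = npool)
    jac <- ov / (length(qk) + pool_sizes - ov)
    which(jac >= cutoff)
  })
}

#' Greedy identity clustering (CD-HIT-like)
#'
#' Sequences are sorted longest-first; each joins the first cluster whose
#' representative (its founding, longest member) it matches at
#' `>= threshold` global identity, otherwise it founds a new cluster.
#'
#' @param sequences Character vector of sequences.
#' @param threshold Identity threshold; `>=` is redundant (default 0.40).
#' @param word_filter 3-mer Jaccard cutoff below which alignment is
#'   skipped (speed heuristic); 0 disables the screen.
#' @return List with `membership` (cluster index per sequence),
#'   `clusters` (list of member indices) and `representatives` (index of
#'   each cluster's representative).
#' @export
identity_cluster <- function(sequences, threshold = 0.40, word_filter = 0) {
  n <- length(sequences)
  if (n == 0) stop("no sequences to cluster")
  ord <- order(nchar(sequences), decreasing = TRUE)
  reps <- integer(0)
  membership <- integer(n)
  for (i in ord) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      r <- reps[ci]
      if (word_filter > 0 &&
          kmer_jaccard(sequences[i], sequences[r]) < word_filter) next
      if (seq_identity(sequences[i], sequences[r]) >= threshold) {
        membership[i] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      membership[i] <- length(reps)
    }
  }
  list(membership = membership,
       clusters = split(seq_len(n), membership),
       representatives = reps)
}
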