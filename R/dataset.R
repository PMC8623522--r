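# Dataset construction: consensus order/disorder labels, IDR-plus-flank
# fragment selection, topology-aware class balancing, and leakage-guarded
# train/validation/test splits.

#' Annotated protein container
#'
#' @param id Protein identifier.
#' @param sequence Amino-acid sequence (single string).
#' @param topology A `topology_track` (see [parse_topology()]).
#' @param labels Optional per-residue label vector over `D` (disordered),
#'   `O` (ordered), `U` (unobserved).
#' @param rsa Optional per-residue relative accessibility in `[0, 1]`.
#' @param profile Optional `profile_matrix`; defaults to
#'   [pseudo_profile()] at feature time.
#' @export
annotated_protein <- function(id, sequence, topology, labels = NULL,
                              rsa = NULL, profile = NULL) {
  L <- nchar(sequence)
  stopifnot(length(topology) == L)
  if (!is.null(labels)) {
    stopifnot(length(labels) == L, all(labels %in% c("D", "O", "U")))
  }
  structure(list(id = id, sequence = sequence, topology = topology,
                 labels = labels, rsa = rsa, profile = profile),
            class = "annotated_protein")
}

#' Consensus order/disorder labels from repeated observations
#'
#' A residue is labelled disordered when at least `threshold` of the
#' observation tracks mark it missing, ordered when at least `threshold`
#' mark it observed, and unobserved otherwise. Exactly 90% agreement
#' counts as agreement.
#'
#' @param observations List of logical vectors (TRUE = residue missing
#'   from the structure), all the same length.
#' @param threshold Agreement fraction (default 0.9).
#' @return Character label vector over `D`/`O`/`U`.
#' @export
consensus_labels <- function(observations, threshold = 0.9) {
  if (length(observations) == 0) stop("no observation tracks")
  L <- unique(lengths(observations))
  if (length(L) != 1) stop("observation tracks differ in length")
  M <- do.call(rbind, lapply(observations, as.logical))
  frac_missing <- colMeans(M)
  ifelse(frac_missing >= threshold, "D",
         ifelse(1 - frac_missing >= threshold, "O", "U"))
}

new_fragment <- function(protein, start, end, kind, category) {
  start <- as.integer(unname(start))
  end <- as.integer(unname(end))
  structure(list(
    parent_id = protein$id,
    start = start, end = end, kind = kind,
    sequence = substr(protein$sequence, start, end),
    topology = unclass(protein$topology)[start:end],
    labels = protein$labels[start:end],
    category = category[start:end],
    id = paste0(protein$id, ":", start, "-", end, ":", kind)),
    class = "fragment")
}

#' Select training/evaluation fragments from a labelled protein
#'
#' Every maximal disordered run becomes one `idr_with_flanks` fragment
#' together with up to `flank` ordered residues on each side (flanks stop
#' at unobserved residues and at the protein ends). In addition,
#' `ordered_random` fragments are drawn from fully ordered stretches: one
#' per IDR fragment (one in total for fully ordered proteins), with
#' target lengths sampled from the protein's IDR-fragment length
#' distribution (fallback `2*flank + 5`).
#'
#' @param protein An [annotated_protein()] with labels.
#' @param flank Maximum ordered flank length (default 15).
#' @param seed Seed for the placement of ordered fragments.
#' @return List of `fragment` objects.
#' @export
select_fragments <- function(protein, flank = 15L, seed = 1L) {
  if (is.null(protein$labels)) stop("protein has no label track")
  lab <- protein$labels
  L <- length(lab)
  category <- categorize(protein$topology)
  frs <- list()

  idr_runs <- true_runs(lab == "D")
  for (i in seq_len(nrow(idr_runs))) {
    s <- idr_runs[i, "start"]; e <- idr_runs[i, "end"]
    ls <- s
    while (ls > 1L && s - ls < flank && lab[ls - 1L] == "O") ls <- ls - 1L
    re <- e
    while (re < L && re - e < flank && lab[re + 1L] == "O") re <- re + 1L
    frs[[length(frs) + 1L]] <-
      new_fragment(protein, ls, re, "idr_with_flanks", category)
  }

  n_ord <- max(length(frs), 1L)
  idr_lens <- vapply(frs, function(f) f$end - f$start + 1L, integer(1))
  if (length(idr_lens) == 0) idr_lens <- 2L * flank + 5L
  ord_runs <- true_runs(lab == "O")
  if (nrow(ord_runs) > 0) {
    with_seed(seed, {
      for (k in seq_len(n_ord)) {
        len <- sample(idr_lens, 1L)
        run_len <- ord_runs[, "end"] - ord_runs[, "start"] + 1L
        wt <- pmax(run_len - pmin(len, run_len) + 1L, 1L)
        ri <- sample.int(nrow(ord_runs), 1L, prob = wt)
        use <- min(len, run_len[ri])
        s <- ord_runs[ri, "start"] +
          sample.int(run_len[ri] - use + 1L, 1L) - 1L
        frs[[length(frs) + 1L]] <-
          new_fragment(protein, s, s + use - 1L, "ordered_random",
                       category)
      }
    })
  }
  frs
}

# one row per labelled, non-membrane residue across fragments,
# deduplicated by parent position
fragment_residue_table <- function(fragments) {
  rows <- lapply(fragments, function(f) {
    pos <- seq.int(f$start, f$end)
    keep <- f$labels %in% c("D", "O") &
      as.character(f$category) != "MEMBRANE" &
      !is.na(f$category)
    n <- sum(keep)
    data.frame(parent_id = rep(f$parent_id, n), pos = pos[keep],
               category = as.character(f$category)[keep],
               label = f$labels[keep],
               fragment_id = rep(f$id, n), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) == 0)
    return(data.frame(parent_id = character(), pos = integer(),
                      category = character(), label = character(),
                      fragment_id = character()))
  tab[!duplicated(paste(tab$parent_id, tab$pos)), , drop = FALSE]
}

#' Balance disordered vs ordered residues within each compartment
#'
#' For each of the four compartments, the majority class is downsampled
#' so the class counts differ by at most `tolerance` (relative to the
#' larger count). Compartments missing one class entirely are excluded
#' with a warning.
#'
#' @param fragments List of `fragment` objects.
#' @param tolerance Maximum relative class imbalance (default 0.10).
#' @param seed Seed for the downsampling draw.
#' @return Named list (one entry per retained compartment) of residue
#'   data frames with columns `parent_id`, `pos`, `category`, `label`,
#'   `fragment_id`.
#' @export
balance_categories <- function(fragments, tolerance = 0.10, seed = 1L) {
  tab <- fragment_residue_table(fragments)
  out <- list()
  for (cat in CNN_CATEGORIES) {
    sub <- tab[tab$category == cat, , drop = FALSE]
    nd <- sum(sub$label == "D"); no <- sum(sub$label == "O")
    if (nd == 0 || no == 0) {
      warning("compartment ", cat, " lacks ",
              if (nd == 0) "disordered" else "ordered",
              " residues and is excluded from training")
      next
    }
    m <- min(nd, no)
    cap <- max(m, floor(m * (1 + tolerance)))
    keep_major <- with_seed(seed + match(cat, CNN_CATEGORIES), {
      major <- which(sub$label == (if (nd > no) "D" else "O"))
      if (length(major) > cap) sample(major, cap) else major
    })
    minor <- which(sub$label == (if (nd > no) "O" else "D"))
    sel <- sort(c(minor, keep_major))
    out[[cat]] <- sub[sel, , drop = FALSE]
  }
  out
}

#' Assign fragments to train/validation/test with an identity guard
#'
#' Fragments are shuffled under `seed` and cut into the three partitions
#' at the given ratios; a repair pass then moves any test fragment
#' sharing `>= threshold` global identity with a train or validation
#' fragment into the training set, so the published leakage guard holds
#' by construction.
#'
#' @param fragments List of `fragment` objects.
#' @param ratios Named numeric `c(train=, validation=, test=)` summing
#'   to 1.
#' @param seed Shuffle seed.
#' @param threshold Identity guard (default 0.40, inclusive).
#' @param word_filter 3-mer Jaccard screen passed to the identity check
#'   (0 disables; see [identity_cluster()]).
#' @return Data frame with columns `fragment_id`, `split`; the seed and
#'   number of repairs are attached as attributes.
#' @export
split_fragments <- function(fragments,
                            ratios = c(train = 0.7, validation = 0.15,
                                       test = 0.15),
                            seed = 1L, threshold = 0.40,
                            word_filter = 0.08) {
  stopifnot(abs(sum(ratios) - 1) < 1e-8)
  n <- length(fragments)
  if (n == 0) stop("no fragments to split")
  sizes <- diff(c(0, floor(cumsum(ratios) * n)))
  split <- rep(names(ratios), sizes)
  ord <- with_seed(seed, sample.int(n))
  assignment <- character(n)
  assignment[ord] <- split

  seqs <- vapply(fragments, function(f) f$sequence, character(1))
  moved <- 0L
  repeat {  # iterate: moving a fragment enlarges the train pool
    test_idx <- which(assignment == "test")
    pool <- which(assignment != "test")
    cand <- word_filter_candidates(seqs[test_idx], seqs[pool],
                                   word_filter)
    moved_pass <- 0L
    for (t in seq_along(test_idx)) {
      i <- test_idx[t]
      for (j in pool[cand[[t]]]) {
        if (seq_identity(seqs[i], seqs[j]) >= threshold) {
          assignment[i] <- "train"
          moved_pass <- moved_pass + 1L
          break
        }
      }
    }
    moved <- moved + moved_pass
    if (moved_pass == 0L) break
  }
  if (!any(assignment == "test"))
    stop("identity guard emptied the test set: all fragments are ",
         "mutually redundant at ", threshold * 100, "% identity")
  structure(data.frame(
    fragment_id = vapply(fragments, function(f) f$id, character(1)),
    split = assignment, stringsAsFactors = FALSE),
    seed = seed, repaired = moved)
}
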