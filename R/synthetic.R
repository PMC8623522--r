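# Synthetic transmembrane proteins with ground-truth topology and
# disorder, so the whole pipeline trains and evaluates without external
# data. Disorder is carried by compositional bias (disorder-promoting
# vs order-promoting alphabets) plus a surrogate accessibility channel.

#' Synthetic corpus scenario
#'
#' Defines the generative conditions: protein architecture (alternating
#' inside/outside loops separated by hydrophobic membrane segments),
#' side-specific disorder placement, compositional bias strengths, label
#' noise and the accessibility surrogate.
#'
#' @param n_proteins Corpus size.
#' @param tm_count_range Range of membrane-segment counts per protein.
#' @param tm_len_range Membrane segment length range (residues).
#' @param loop_mean,tail_mean Mean lengths of inter-TM loops and
#'   terminal tails (geometric tails on top of a minimum length).
#' @param p_disorder_inside,p_disorder_outside Per-segment probability
#'   that a cytosolic / extracellular segment carries a disordered
#'   stretch (inside > outside so compartment routing has signal).
#' @param disorder_frac_range Fraction of a segment converted to
#'   disorder when a stretch is planted.
#' @param min_idr Minimum planted IDR length.
#' @param bias_disorder,bias_order,bias_tm Compositional enrichment
#'   multipliers for the disorder-promoting, order-promoting and
#'   hydrophobic alphabets in their respective segment types.
#' @param label_noise Per-residue probability of flipping the D/O label.
#' @param unobs_prob Probability that a protein carries one short
#'   unobserved (`U`) run.
#' @param rsa_means,rsa_sd Accessibility surrogate: means for
#'   (disordered, ordered, membrane) residues and Gaussian noise sd.
#' @return A `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(n_proteins = 500L,
                               tm_count_range = c(1L, 4L),
                               tm_len_range = c(17L, 25L),
                               loop_mean = 30, tail_mean = 50,
                               p_disorder_inside = 0.5,
                               p_disorder_outside = 0.25,
                               disorder_frac_range = c(0.4, 0.9),
                               min_idr = 6L,
                               bias_disorder = 1.5, bias_order = 1.3,
                               bias_tm = 4,
                               label_noise = 0.03, unobs_prob = 0.3,
                               rsa_means = c(disordered = 0.62,
                                             ordered = 0.40,
                                             membrane = 0.12),
                               rsa_sd = 0.15) {
  stopifnot(p_disorder_inside >= 0, p_disorder_inside <= 1,
            p_disorder_outside >= 0, p_disorder_outside <= 1,
            label_noise >= 0, label_noise <= 1)
  structure(as.list(environment()), class = "synthetic_scenario")
}

segment_weights <- function(scenario, type) {
  w <- stats::setNames(rep(1, 20), AA_STANDARD)
  if (type == "disordered") {
    w[AA_DISORDER_PROMOTING] <- scenario$bias_disorder
    w[AA_ORDER_PROMOTING] <- 1 / scenario$bias_disorder
  } else if (type == "ordered") {
    w[AA_ORDER_PROMOTING] <- scenario$bias_order
    w[AA_DISORDER_PROMOTING] <- 1 / scenario$bias_order
  } else if (type == "membrane") {
    w[AA_TM_HYDROPHOBIC] <- scenario$bias_tm
    w[c("D", "E", "K", "R", "H", "N", "Q")] <- 0.1
  }
  w / sum(w)
}

sample_aa <- function(n, weights) {
  sample(AA_STANDARD, n, replace = TRUE, prob = weights)
}

seg_len <- function(minimum, mean) {
  minimum + stats::rgeom(1, 1 / max(mean - minimum, 1))
}

#' Generate one synthetic transmembrane protein
#'
#' Alternating loop/tail and membrane segments with planted disordered
#' stretches in non-membrane segments; labels equal the planted truth
#' except at the scenario's noise rate (the clean truth is attached as
#' attribute `truth`).
#'
#' @param scenario A [synthetic_scenario()].
#' @param id Protein identifier.
#' @return An [annotated_protein()] with `labels`, `rsa`, and attribute
#'   `truth`.
#' @export
generate_protein <- function(scenario, id = "synth1") {
  n_tm <- sample(scenario$tm_count_range[1]:scenario$tm_count_range[2], 1)
  side <- sample(c("I", "O"), 1)
  segs <- list()
  for (k in seq_len(n_tm + 1L)) {
    is_tail <- k == 1L || k == n_tm + 1L
    len <- seg_len(if (is_tail) 10L else 6L,
                   if (is_tail) scenario$tail_mean else scenario$loop_mean)
    segs[[length(segs) + 1L]] <- list(type = side, len = len)
    if (k <= n_tm) {
      tm_len <- sample(scenario$tm_len_range[1]:scenario$tm_len_range[2],
                       1)
      segs[[length(segs) + 1L]] <- list(type = "M", len = tm_len)
      side <- if (side == "I") "O" else "I"
    }
  }

  aa <- character(0); topo <- character(0); truth <- character(0)
  for (sg in segs) {
    if (sg$type == "M") {
      aa <- c(aa, sample_aa(sg$len, segment_weights(scenario, "membrane")))
      topo <- c(topo, rep("M", sg$len))
      truth <- c(truth, rep("O", sg$len))
      next
    }
    p_dis <- if (sg$type == "I") scenario$p_disorder_inside
             else scenario$p_disorder_outside
    seg_truth <- rep("O", sg$len)
    if (sg$len >= scenario$min_idr + 2L && stats::runif(1) < p_dis) {
      frac <- stats::runif(1, scenario$disorder_frac_range[1],
                           scenario$disorder_frac_range[2])
      dlen <- max(scenario$min_idr, round(frac * sg$len))
      dlen <- min(dlen, sg$len)
      at <- sample.int(sg$len - dlen + 1L, 1)
      seg_truth[at:(at + dlen - 1L)] <- "D"
    }
    seg_aa <- character(sg$len)
    nd <- sum(seg_truth == "D")
    if (nd > 0)
      seg_aa[seg_truth == "D"] <-
        sample_aa(nd, segment_weights(scenario, "disordered"))
    if (nd < sg$len)
      seg_aa[seg_truth == "O"] <-
        sample_aa(sg$len - nd, segment_weights(scenario, "ordered"))
    aa <- c(aa, seg_aa)
    topo <- c(topo, rep(sg$type, sg$len))
    truth <- c(truth, seg_truth)
  }

  L <- length(aa)
  labels <- truth
  flip <- stats::runif(L) < scenario$label_noise & topo != "M"
  labels[flip] <- ifelse(labels[flip] == "D", "O", "D")
  if (stats::runif(1) < scenario$unobs_prob) {
    ulen <- sample(5:15, 1)
    at <- sample.int(max(L - ulen, 1L), 1)
    labels[at:(at + ulen - 1L)] <- "U"
  }

  means <- scenario$rsa_means[ifelse(topo == "M", "membrane",
                                     ifelse(truth == "D", "disordered",
                                            "ordered"))]
  rsa <- clamp01(means + stats::rnorm(L, sd = scenario$rsa_sd))

  p <- annotated_protein(id, paste(aa, collapse = ""),
                         new_topology_track(topo), labels = labels,
                         rsa = rsa)
  attr(p, "truth") <- truth
  p
}

#' Generate a reproducible synthetic corpus
#'
#' @param scenario A [synthetic_scenario()].
#' @param seed Corpus seed; identical seeds give identical corpora.
#' @return List of [annotated_protein()] objects.
#' @export
generate_corpus <- function(scenario = synthetic_scenario(), seed = 1L) {
  with_seed(seed, lapply(seq_len(scenario$n_proteins), function(i)
    generate_protein(scenario, id = sprintf("synth%04d", i))))
}

#' Composition-only disorder baseline
#'
#' Windowed disorder-propensity score: the mean over a +/-`half_width`
#' window of +1 for disorder-promoting residues, -1 for order-promoting
#' residues, 0 otherwise, mapped to `[0, 1]`. Serves as the sanity floor
#' the trained ensemble must beat.
#'
#' @param protein An [annotated_protein()] (or a sequence string).
#' @param half_width Window half-width.
#' @return Score track in `[0, 1]`.
#' @export
baseline_composition_score <- function(protein, half_width = 5L) {
  sequence <- if (is.character(protein)) protein else protein$sequence
  aa <- strsplit(sequence, "")[[1]]
  w <- numeric(length(aa))
  w[aa %in% AA_DISORDER_PROMOTING] <- 1
  w[aa %in% AA_ORDER_PROMOTING] <- -1
  (smooth_scores(w, half_width) + 1) / 2
}
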