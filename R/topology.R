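# Per-residue membrane topology: parsing, membrane distance, and the
# four-compartment partition of non-membrane residues.

#' Topology label alphabet
#'
#' Per-residue topology labels: `I` (inside/cytosolic), `O` (outside/
#' extracellular), `M` (membrane-embedded), `L` (re-entrant loop).
#' Re-entrant residues sit in the bilayer and are treated as membrane
#' throughout the pipeline (excluded from compartment scoring, zero input
#' to the smoother).
#'
#' @export
TOPOLOGY_ALPHABET <- c("I", "O", "M", "L")

#' Residue compartment categories
#'
#' Non-membrane residues fall into four compartments by side and distance
#' to the nearest membrane residue: extracellular vs cytosolic crossed with
#' distant (>15 residues) vs proximal (<=15 residues). Membrane (and
#' re-entrant) residues form the fifth, non-scored category.
#'
#' @export
RESIDUE_CATEGORIES <- c("EXTRA_DISTANT", "EXTRA_PROXIMAL",
                        "INTRA_DISTANT", "INTRA_PROXIMAL", "MEMBRANE")

#' Compartments scored by a convolutional model
#' @export
CNN_CATEGORIES <- RESIDUE_CATEGORIES[1:4]

new_topology_track <- function(labels) {
  structure(labels, class = "topology_track")
}

#' Parse per-residue membrane topology
#'
#' Accepts either a single-line per-residue string over the alphabet
#' `I/O/M/L` or a region table with 1-based closed coordinates
#' (columns `start`, `end`, `label`). For region input, positions not
#' covered by any region are inferred: loops alternate side across each
#' membrane segment, starting from `first_side`.
#'
#' @param x Topology string, or a data.frame with columns `start`, `end`,
#'   `label` (1-based, closed intervals).
#' @param length Protein length; required for region input, optional
#'   (checked) for string input.
#' @param first_side Side assumed for the segment preceding the first
#'   membrane segment when region input omits loop labels (`"I"` or `"O"`).
#' @param require_membrane Reject tracks without any membrane residue
#'   (the predictor targets transmembrane proteins).
#' @return A `topology_track`: character vector of per-residue labels.
#' @examples
#' parse_topology("IIIMMMOOO")
#' parse_topology(data.frame(start = 4, end = 6, label = "M"), length = 9)
#' @export
parse_topology <- function(x, length = NULL, first_side = "I",
                           require_membrane = TRUE) {
  if (is.character(x) && base::length(x) == 1L) {
    labels <- strsplit(toupper(x), "")[[1]]
    bad <- setdiff(unique(labels), TOPOLOGY_ALPHABET)
    if (base::length(bad) > 0)
      stop("unknown topology symbol(s): ", paste(bad, collapse = ", "))
    if (!is.null(length) && base::length(labels) != length)
      stop("topology length (", base::length(labels),
           ") does not match sequence length (", length, ")")
  } else if (is.data.frame(x)) {
    if (is.null(length)) stop("'length' is required for region input")
    need <- c("start", "end", "label")
    if (!all(need %in% names(x)))
      stop("region table must have columns start, end, label")
    x$label <- toupper(as.character(x$label))
    bad <- setdiff(unique(x$label), TOPOLOGY_ALPHABET)
    if (base::length(bad) > 0)
      stop("unknown topology symbol(s): ", paste(bad, collapse = ", "))
    if (any(x$start < 1 | x$end > length | x$start > x$end))
      stop("region coordinates outside 1..", length, " or start > end")
    labels <- rep(NA_character_, length)
    for (i in seq_len(nrow(x))) {
      idx <- x$start[i]:x$end[i]
      if (any(!is.na(labels[idx])))
        stop("overlapping regions in topology input")
      labels[idx] <- x$label[i]
    }
    labels <- infer_sides(labels, first_side)
  } else {
    stop("topology input must be a single string or a region data.frame")
  }
  if (require_membrane && !any(labels %in% c("M", "L")))
    stop("no membrane segment in topology: the predictor targets ",
         "transmembrane proteins")
  new_topology_track(labels)
}

# fill NA gaps between declared regions: sides alternate across each
# membrane segment, starting with `first_side` before the first one
infer_sides <- function(labels, first_side) {
  stopifnot(first_side %in% c("I", "O"))
  side <- first_side
  flip <- function(s) if (s == "I") "O" else "I"
  i <- 1L
  n <- length(labels)
  while (i <= n) {
    if (is.na(labels[i])) {
      labels[i] <- side
      i <- i + 1L
    } else if (labels[i] %in% c("M", "L")) {
      while (i <= n && !is.na(labels[i]) && labels[i] %in% c("M", "L"))
        i <- i + 1L
      side <- flip(side)
    } else {
      side <- labels[i]
      i <- i + 1L
    }
  }
  labels
}

is_membrane_label <- function(track) {
  unclass(track) %in% c("M", "L")
}

#' Distance to the nearest membrane residue
#'
#' Minimum sequence-position distance from each residue to any
#' membrane-labelled (`M`/`L`) residue; membrane residues have distance 0.
#'
#' @param track A `topology_track`.
#' @param index Optional residue position(s); default all residues.
#' @return Integer vector of distances.
#' @export
membrane_distance <- function(track, index = NULL) {
  mem <- is_membrane_label(track)
  n <- length(mem)
  if (!any(mem)) stop("no membrane residue in topology track")
  # two linear sweeps: nearest membrane to the left, then to the right
  d <- rep.int(n, n)
  last <- -Inf
  for (i in seq_len(n)) {
    if (mem[i]) last <- i
    d[i] <- i - last
  }
  nxt <- Inf
  for (i in rev(seq_len(n))) {
    if (mem[i]) nxt <- i
    d[i] <- min(d[i], nxt - i)
  }
  d <- as.integer(d)
  if (is.null(index)) d else {
    if (any(index < 1 | index > n)) stop("index outside track")
    d[index]
  }
}

#' Assign each residue to a topology compartment
#'
#' Non-membrane residues are split by side (extracellular vs cytosolic)
#' and membrane distance: proximal when within `d_prox` residues of the
#' nearest membrane residue (inclusive), distant beyond it. Membrane and
#' re-entrant residues map to `MEMBRANE`.
#'
#' @param track A `topology_track`.
#' @param d_prox Proximal/distant boundary in residues (default 15;
#'   distance 15 is proximal, 16 is distant).
#' @return Factor of length `length(track)` with levels
#'   [RESIDUE_CATEGORIES].
#' @export
categorize <- function(track, d_prox = 15L) {
  labels <- unclass(track)
  d <- membrane_distance(track)
  out <- character(length(labels))
  mem <- is_membrane_label(track)
  out[mem] <- "MEMBRANE"
  prox <- !mem & d <= d_prox
  dist <- !mem & d > d_prox
  out[labels == "O" & prox] <- "EXTRA_PROXIMAL"
  out[labels == "O" & dist] <- "EXTRA_DISTANT"
  out[labels == "I" & prox] <- "INTRA_PROXIMAL"
  out[labels == "I" & dist] <- "INTRA_DISTANT"
  factor(out, levels = RESIDUE_CATEGORIES)
}
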