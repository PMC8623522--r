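# Output modes: specific (CNN track, +/-4 smoothing, 0.65 cutoff) and
# sensitive (smoother track, +/-7 smoothing), with the display rescaling
# that maps the cutoff onto 0.5.

#' Moving-average smoothing of a score track
#'
#' Centred moving average over up to `2*half_width + 1` positions,
#' truncated at the sequence ends. Membrane positions neither contribute
#' to their neighbours' averages nor receive one (their output is 0).
#'
#' @param scores Numeric score track.
#' @param half_width Smoothing half-width in residues (0 = identity).
#' @param membrane Optional logical track of membrane positions.
#' @return Smoothed track of the same length.
#' @export
smooth_scores <- function(scores, half_width, membrane = NULL) {
  L <- length(scores)
  if (L == 0) stop("empty score track")
  if (half_width < 0) stop("half_width must be >= 0")
  if (is.null(membrane)) membrane <- rep(FALSE, L)
  w <- ifelse(membrane, 0, scores)
  v <- as.numeric(!membrane)
  cw <- c(0, cumsum(w)); cv <- c(0, cumsum(v))
  a <- pmax(1L, seq_len(L) - half_width)
  b <- pmin(L, seq_len(L) + half_width)
  num <- cw[b + 1L] - cw[a]
  den <- cv[b + 1L] - cv[a]
  out <- ifelse(den > 0, num / den, 0)
  out[membrane] <- 0
  out
}

#' Rescale scores so the decision cutoff displays as 0.5
#'
#' Piecewise-linear, strictly increasing map sending `[0, cutoff]` to
#' `[0, 0.5]` and `[cutoff, 1]` to `[0.5, 1]`, so a residue is called
#' disordered exactly when its display score reaches 0.5.
#'
#' @param score Scores in `[0, 1]`.
#' @param cutoff Decision cutoff in `(0, 1)` (default 0.65).
#' @return Display scores in `[0, 1]`.
#' @export
rescale_scores <- function(score, cutoff = 0.65) {
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must be inside (0, 1)")
  ifelse(score <= cutoff,
         0.5 * score / cutoff,
         0.5 + 0.5 * (score - cutoff) / (1 - cutoff))
}

#' Binary disorder calls
#'
#' @param smoothed Smoothed score track.
#' @param cutoff Decision cutoff; `>=` is disordered (boundary
#'   inclusive).
#' @return Logical vector (TRUE = disordered).
#' @export
call_binary <- function(smoothed, cutoff = 0.65) {
  smoothed >= cutoff
}

#' Per-residue disorder prediction for one protein
#'
#' Runs the compartment CNNs and the recurrent smoother and derives both
#' published output modes: specific (CNN track, +/-4 smoothing) and
#' sensitive (smoother track, +/-7 smoothing), each thresholded at the
#' configured cutoff and rescaled for display.
#'
#' @param ensemble A trained `compartment_ensemble`.
#' @param protein An [annotated_protein()] (labels not required).
#' @return Data frame with one row per residue: `position`, `residue`,
#'   `topology`, `category`, `raw`, `refined`, and per mode the
#'   `smoothed_*`, `display_*` and `call_*` columns.
#' @export
predict_disorder <- function(ensemble, protein) {
  rows <- protein_feature_rows(protein, ensemble$schema)
  raw <- cnn_predict(ensemble, protein, rows = rows)
  refined <- smoother_predict(ensemble$smoother, raw, rows$category)
  mem <- as.character(rows$category) == "MEMBRANE"
  cfg <- ensemble$config
  sm_spec <- smooth_scores(raw, cfg$smooth_specific, mem)
  sm_sens <- smooth_scores(refined, cfg$smooth_sensitive, mem)
  data.frame(
    protein_id = protein$id,
    position = seq_len(rows$L),
    residue = strsplit(protein$sequence, "")[[1]],
    topology = unclass(protein$topology),
    category = as.character(rows$category),
    raw = raw,
    refined = refined,
    smoothed_specific = sm_spec,
    smoothed_sensitive = sm_sens,
    display_specific = rescale_scores(sm_spec, cfg$cutoff),
    display_sensitive = rescale_scores(sm_sens, cfg$cutoff),
    call_specific = call_binary(sm_spec, cfg$cutoff),
    call_sensitive = call_binary(sm_sens, cfg$cutoff),
    stringsAsFactors = FALSE)
}
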