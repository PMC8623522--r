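# Sequence profiles: PSI-BLAST ASCII PSSMs and a substitution-matrix
# fallback used when no externally computed profile is supplied.

# PSI-BLAST prints profile columns in this residue order
PSSM_COLUMN_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                       "L", "K", "M", "F", "P", "S", "T", "W", "V", "Y")

# log-odds scores are divided by this factor before entering the feature
# matrix so profile channels sit on a roughly unit scale
PSSM_SCALE <- 0.1

blosum62_profile_columns <- function() {
  bl <- get_blosum62()
  bl[AA_STANDARD, AA_STANDARD]
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

new_profile_matrix <- function(values, source) {
  stopifnot(ncol(values) == 20, all(is.finite(values)))
  colnames(values) <- AA_STANDARD
  structure(values, source = source, class = c("profile_matrix", "matrix"))
}

#' Substitution-matrix pseudo-profile
#'
#' Deterministic stand-in for a PSI-BLAST profile: row i is the BLOSUM62
#' column of residue i, rescaled by `scale`. Unknown residues (`X`) get a
#' zero row.
#'
#' @param sequence Amino-acid sequence (single string).
#' @param scale Multiplicative rescaling of the log-odds scores.
#' @return An `L x 20` `profile_matrix` (columns in alphabetical
#'   one-letter order).
#' @export
pseudo_profile <- function(sequence, scale = PSSM_SCALE) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  cols <- blosum62_profile_columns()
  vals <- matrix(0, nrow = length(aa), ncol = 20)
  known <- aa %in% AA_STANDARD
  if (any(known)) vals[known, ] <- cols[aa[known], , drop = FALSE] * scale
  new_profile_matrix(vals, source = "substitution_fallback")
}

#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the classic `psiblast -out_ascii_pssm` dialect: a header line
#' naming the 20 score columns, then one row per position with the
#' position index, the query residue, and 20 integer log-odds scores
#' (further columns, if present, are ignored).
#'
#' @param path Path to the PSSM file (or a character vector of its lines).
#' @param sequence Optional sequence; if given, the residue column must
#'   match it.
#' @param scale Rescaling applied to the scores (same convention as
#'   [pseudo_profile()]).
#' @return A `profile_matrix`.
#' @export
read_pssm <- function(path, sequence = NULL, scale = PSSM_SCALE) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- lines[nzchar(trimws(lines))]
  toks <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
  hdr <- which(vapply(toks, function(t)
    length(t) >= 20 && all(PSSM_COLUMN_ORDER %in% t[1:20]), logical(1)))[1]
  if (is.na(hdr)) stop("malformed PSSM: no column header line found")
  col_order <- toks[[hdr]][1:20]
  rows <- toks[(hdr + 1):length(toks)]
  rows <- Filter(function(t) length(t) >= 22 && grepl("^[0-9]+$", t[1]), rows)
  if (length(rows) == 0) stop("malformed PSSM: no data rows")
  aa <- vapply(rows, function(t) t[2], character(1))
  sc <- t(vapply(rows, function(t) {
    v <- suppressWarnings(as.numeric(t[3:22]))
    if (any(is.na(v))) stop("malformed PSSM: non-numeric score")
    v
  }, numeric(20)))
  colnames(sc) <- col_order
  sc <- sc[, AA_STANDARD, drop = FALSE]
  if (!is.null(sequence)) {
    seq_aa <- strsplit(toupper(sequence), "")[[1]]
    if (length(seq_aa) != nrow(sc))
      stop("PSSM has ", nrow(sc), " rows but sequence has ",
           length(seq_aa), " residues")
    mism <- which(aa != seq_aa & seq_aa != "X" & aa != "X")
    if (length(mism) > 0)
      stop("PSSM residue column disagrees with sequence at position ",
           mism[1])
  }
  new_profile_matrix(sc * scale, source = "external_pssm")
}

#' Write a profile matrix in PSI-BLAST ASCII layout
#'
#' @param profile A `profile_matrix`.
#' @param sequence The corresponding sequence.
#' @param path Output file.
#' @param scale The scale the profile was read/built with; values are
#'   divided by it so a write/read round-trip is the identity.
#' @export
write_pssm <- function(profile, sequence, path, scale = PSSM_SCALE) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  stopifnot(length(aa) == nrow(profile))
  vals <- unclass(profile)[, PSSM_COLUMN_ORDER, drop = FALSE] / scale
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("", "Last position-specific scoring matrix computed",
               paste0("   ", paste(sprintf("%3s", PSSM_COLUMN_ORDER),
                                   collapse = " "))), con)
  for (i in seq_along(aa)) {
    writeLines(paste0(sprintf("%5d %s ", i, aa[i]),
                      paste(sprintf("%3d", round(vals[i, ])),
                            collapse = " "),
                      " ", paste(rep("0", 22), collapse = " ")), con)
  }
  invisible(path)
}
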