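# The versioned 39-column feature schema and the 11x39 window matrix
# assembly feeding the compartment CNNs.

#' Default per-position feature schema
#'
#' Each of the 11 window positions carries 39 named features:
#' 20 profile channels (PSSM or substitution fallback), 9 amino-acid
#' scale channels, 3 windowed ProtParam descriptors, 4 one-hot topology
#' compartment indicators (membrane positions are all-zero), 1 relative
#' accessibility, 1 low-complexity flag, and 1 validity indicator
#' (0 marks padding rows beyond the sequence ends).
#'
#' @param half_width Window half-width (default 5: an 11-row matrix).
#' @return A `feature_schema` list with `columns`, `groups`,
#'   `continuous` (columns subject to z-normalization), `half_width`,
#'   `version` and `hash`.
#' @export
feature_schema <- function(half_width = 5L) {
  cols <- c(paste0("profile.", AA_STANDARD),
            paste0("scale.", names(AA_SCALE_SET())),
            c("protparam.mw", "protparam.pi", "protparam.instability"),
            paste0("cat.", CNN_CATEGORIES),
            "rsa", "lowcomplexity", "valid")
  groups <- c(rep("profile", 20), rep("scale", 9), rep("protparam", 3),
              rep("topology", 4), "accessibility", "lowcomplexity",
              "validity")
  continuous <- groups %in% c("profile", "scale", "protparam",
                              "accessibility")
  schema <- list(columns = cols, groups = groups, continuous = continuous,
                 half_width = as.integer(half_width), version = "1")
  schema$hash <- schema_hash(schema)
  class(schema) <- "feature_schema"
  schema
}

schema_hash <- function(schema) {
  txt <- paste(c(schema$version, schema$half_width, schema$columns),
               collapse = "|")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

#' Constant-fallback accessibility track
#'
#' Used when no externally predicted relative solvent accessibility is
#' supplied.
#'
#' @param length Protein length.
#' @param value Constant RSA value in `[0, 1]`.
#' @export
accessibility_fallback <- function(length, value = 0.5) {
  structure(rep(value, length), source = "constant_fallback")
}

#' Read a per-residue accessibility TSV
#'
#' Expects columns `index  residue  rsa` (1-based); values are clamped to
#' `[0, 1]`.
#'
#' @param path File path (or character vector of lines).
#' @param length Expected protein length.
#' @export
read_accessibility <- function(path, length) {
  df <- utils::read.table(path, header = FALSE,
                          col.names = c("index", "residue", "rsa"))
  rsa <- rep(NA_real_, length)
  if (any(df$index < 1 | df$index > length))
    stop("accessibility index outside 1..", length)
  rsa[df$index] <- df$rsa
  if (any(is.na(rsa))) stop("accessibility track incomplete")
  structure(pmin(1, pmax(0, rsa)), source = "external")
}

# L x 39 matrix: the 39-feature vector each residue contributes when it
# appears at some window position
residue_feature_rows <- function(sequence, track, profile, rsa, lc,
                                 schema = feature_schema()) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  L <- length(aa)
  stopifnot(length(track) == L, nrow(profile) == L, length(rsa) == L,
            length(lc) == L)
  cat <- categorize(track)
  scales <- AA_SCALE_SET()
  sc <- vapply(scales, function(s) {
    v <- rep(0, L)
    known <- aa %in% AA_STANDARD
    v[known] <- s[aa[known]]
    v
  }, numeric(L))
  pp <- protparam_track(sequence, half_width = schema$half_width)
  onehot <- matrix(0, nrow = L, ncol = 4,
                   dimnames = list(NULL, CNN_CATEGORIES))
  ci <- match(as.character(cat), CNN_CATEGORIES)
  has <- !is.na(ci)
  onehot[cbind(which(has), ci[has])] <- 1
  X <- cbind(unclass(profile), sc, pp, onehot, rsa = as.numeric(rsa),
             lowcomplexity = as.numeric(lc), valid = 1)
  colnames(X) <- schema$columns
  X
}

#' Build the windowed feature matrix for one residue
#'
#' Stacks the 39-feature rows of the `2*half_width + 1` positions centred
#' on `center`. Positions beyond the sequence ends are all-zero padding
#' rows with validity 0; membrane positions inside the window contribute
#' their real feature values (they are features of the centre residue,
#' not labelled examples).
#'
#' @param sequence,track,profile,rsa,lc Per-protein inputs (see
#'   [residue_feature_rows()]).
#' @param center 1-based residue position (must be non-membrane).
#' @param schema A [feature_schema()].
#' @return An `11 x 39` numeric matrix (rows = window positions).
#' @export
build_feature_matrix <- function(sequence, track, profile, rsa, lc, center,
                                 schema = feature_schema()) {
  R <- residue_feature_rows(sequence, track, profile, rsa, lc, schema)
  if (is_membrane_label(track)[center])
    stop("center residue is membrane-embedded; only water-exposed ",
         "residues are scored")
  M <- window_stack(R, center, schema)[1, , ]
  dimnames(M) <- list(NULL, schema$columns)
  M
}

# N x 11 x 39 tensor for a batch of centres, with zero padding rows
window_stack <- function(R, centers, schema) {
  h <- schema$half_width
  L <- nrow(R)
  nf <- ncol(R)
  offs <- -h:h
  pos <- outer(centers, offs, `+`)          # N x 11
  inb <- pos >= 1L & pos <= L
  pos_c <- pmin(pmax(pos, 1L), L)
  flat <- R[as.vector(pos_c), , drop = FALSE]   # (N*11) x 39
  flat[!as.vector(inb), ] <- 0
  array(flat, dim = c(length(centers), length(offs), nf))
}

#' @rdname build_feature_matrix
#' @param centers Vector of residue positions; returns the flattened
#'   `N x (11*39)` design matrix (for each feature, the 11 window
#'   positions are contiguous) used for training and batched prediction.
#' @export
feature_tensor <- function(sequence, track, profile, rsa, lc, centers,
                           schema = feature_schema()) {
  R <- residue_feature_rows(sequence, track, profile, rsa, lc, schema)
  A <- window_stack(R, centers, schema)
  matrix(A, nrow = dim(A)[1], ncol = dim(A)[2] * dim(A)[3])
}

# z-normalization of the continuous schema columns; statistics are
# computed on training rows and frozen into the model artifact.
# X is N x (11*nf) position-major; stats are per-feature (length nf).
feature_norm_stats <- function(X, schema) {
  nf <- length(schema$columns)
  npos <- ncol(X) / nf
  A <- array(X, dim = c(nrow(X), npos, nf))
  valid <- A[, , nf] > 0
  mu <- sd <- numeric(nf)
  for (j in which(schema$continuous)) {
    v <- A[, , j][valid]
    mu[j] <- mean(v)
    sd[j] <- stats::sd(v)
    if (!is.finite(sd[j]) || sd[j] < 1e-8) sd[j] <- 1
  }
  list(mu = mu, sd = sd, continuous = schema$continuous)
}

apply_feature_norm <- function(X, stats, schema) {
  nf <- length(schema$columns)
  npos <- ncol(X) / nf
  A <- array(X, dim = c(nrow(X), npos, nf))
  valid <- A[, , nf]                     # keep padding rows all-zero
  for (j in which(stats$continuous))
    A[, , j] <- ((A[, , j] - stats$mu[j]) / stats$sd[j]) * valid
  matrix(A, nrow = nrow(X), ncol = ncol(X))
}
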