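# The compartment ensemble: four per-compartment CNNs over 11x39 window
# matrices plus a bidirectional recurrent smoother, with the training
# pipeline that wires them to the dataset module.

#' Ensemble configuration
#'
#' Architecture and optimisation settings for the compartment ensemble.
#' Defaults: two convolution layers over the 11-position window axis
#' (kernel 3; 32 then 16 channels, ReLU), global average pooling and a
#' sigmoid head; an 8-unit bidirectional tanh recurrent smoother with a
#' truncated 12-step lookback per direction; Adam (lr 1e-3), batch 64,
#' early stopping with patience 10 on validation loss.
#'
#' @param schema Feature schema (see [feature_schema()]).
#' @param channels,kernel CNN channel widths and kernel size.
#' @param hidden,lookback Smoother hidden size and per-direction lookback.
#' @param batch_size,max_epochs,patience,min_delta,lr Optimisation
#'   settings shared by the CNNs and the smoother.
#' @param max_train,max_val Per-compartment caps on training/validation
#'   residues (subsampled beyond the cap to bound runtime).
#' @param max_smoother_train,max_smoother_val Caps on the residue windows
#'   used to fit the smoother.
#' @param cutoff Decision cutoff on smoothed scores (default 0.65).
#' @param smooth_specific,smooth_sensitive Smoothing half-widths of the
#'   two output modes.
#' @param seed Seed for weight initialisation and minibatch order.
#' @export
ensemble_config <- function(schema = feature_schema(),
                            channels = c(32L, 16L), kernel = 3L,
                            hidden = 8L, lookback = 12L,
                            batch_size = 64L, max_epochs = 500L,
                            patience = 10L, min_delta = 1e-4, lr = 1e-3,
                            max_train = 6000L, max_val = 2000L,
                            max_smoother_train = 20000L,
                            max_smoother_val = 5000L,
                            cutoff = 0.65, smooth_specific = 4L,
                            smooth_sensitive = 7L, seed = 1L) {
  if (patience < 1) stop("patience must be >= 1")
  if (length(schema$columns) != 39)
    stop("default architecture expects a 39-column schema, got ",
         length(schema$columns))
  list(schema = schema, channels = channels, kernel = kernel,
       hidden = hidden, lookback = lookback, batch_size = batch_size,
       max_epochs = max_epochs, patience = patience,
       min_delta = min_delta, lr = lr, max_train = max_train,
       max_val = max_val, max_smoother_train = max_smoother_train,
       max_smoother_val = max_smoother_val, cutoff = cutoff,
       smooth_specific = smooth_specific,
       smooth_sensitive = smooth_sensitive, seed = seed)
}

#' Build an untrained compartment ensemble
#'
#' One CNN per non-membrane compartment plus one bidirectional recurrent
#' smoother, with seeded weight initialisation.
#'
#' @param config An [ensemble_config()].
#' @return A `compartment_ensemble` object.
#' @export
build_ensemble <- function(config = ensemble_config()) {
  n_pos <- 2L * config$schema$half_width + 1L
  n_feat <- length(config$schema$columns)
  with_seed(config$seed, {
    cnns <- lapply(CNN_CATEGORIES, function(cat)
      cnn_init(n_pos, n_feat, config$channels, config$kernel))
    names(cnns) <- CNN_CATEGORIES
    smoother <- rnn_init(n_in = 6L, hidden = config$hidden,
                         lookback = config$lookback)
    structure(list(cnns = cnns, smoother = smoother,
                   schema = config$schema, norm_stats = NULL,
                   config = config, trained = FALSE),
              class = "compartment_ensemble")
  })
}

# per-protein feature tracks shared by training and prediction
protein_feature_rows <- function(protein, schema) {
  L <- nchar(protein$sequence)
  profile <- protein$profile %||% pseudo_profile(protein$sequence)
  rsa <- protein$rsa %||% accessibility_fallback(L)
  lc <- seg_mask(protein$sequence)
  list(R = residue_feature_rows(protein$sequence, protein$topology,
                                profile, rsa, lc, schema),
       category = categorize(protein$topology),
       L = L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train one compartment CNN
#'
#' Minibatch Adam with early stopping: training halts once the best
#' validation loss has not improved for `patience` consecutive epochs
#' (or at `max_epochs`), and the weights of the best-validation epoch
#' are returned.
#'
#' @param cnn An initialised CNN parameter list (from [build_ensemble()]).
#' @param X_train,y_train,X_val,y_val Design matrices (rows = residues,
#'   flattened window features) and 0/1 disorder labels.
#' @param config An [ensemble_config()].
#' @return List with `par` (best weights), `history` (per-epoch
#'   validation loss) and `best_epoch`.
#' @export
train_cnn <- function(cnn, X_train, y_train, X_val, y_val, config) {
  if (length(unique(y_train)) < 2)
    stop("single-class training set for compartment CNN")
  batch_fn <- function(par, b) {
    fw <- cnn_forward(par, X_train[b, , drop = FALSE], cache = TRUE)
    cnn_backward(par, fw, y_train[b])
  }
  val_loss_fn <- function(par) bce_loss(cnn_forward(par, X_val), y_val)
  train_loop(cnn, PARAM_NAMES$cnn, nrow(X_train), batch_fn,
             val_loss_fn, config)
}

#' Per-residue raw scores from the compartment CNNs
#'
#' Routes every water-exposed residue to the CNN of its compartment;
#' membrane (and re-entrant) residues carry a raw score of 0 by
#' convention.
#'
#' @param ensemble A trained `compartment_ensemble`.
#' @param protein An [annotated_protein()].
#' @param rows Optional precomputed [protein_feature_rows] list.
#' @return Numeric score track in `[0, 1]`, length = protein length.
#' @export
cnn_predict <- function(ensemble, protein, rows = NULL) {
  if (!isTRUE(ensemble$trained))
    stop("ensemble is untrained; call train_ensemble() first")
  if (is.null(rows)) rows <- protein_feature_rows(protein, ensemble$schema)
  raw <- numeric(rows$L)
  for (cat in CNN_CATEGORIES) {
    centers <- which(rows$category == cat)
    if (length(centers) == 0) next
    A <- window_stack(rows$R, centers, ensemble$schema)
    X <- matrix(A, length(centers), prod(dim(A)[2:3]))
    X <- apply_feature_norm(X, ensemble$norm_stats, ensemble$schema)
    raw[centers] <- cnn_forward(ensemble$cnns[[cat]], X)
  }
  raw
}

# per-residue smoother input: (raw score, 4 compartment indicators,
# membrane bit); membrane residues carry score 0
smoother_input_rows <- function(raw, category) {
  L <- length(raw)
  mem <- as.character(category) == "MEMBRANE"
  onehot <- matrix(0, L, 4, dimnames = list(NULL, CNN_CATEGORIES))
  ci <- match(as.character(category), CNN_CATEGORIES)
  has <- !is.na(ci)
  onehot[cbind(which(has), ci[has])] <- 1
  score <- ifelse(mem, 0, raw)
  cbind(score = score, onehot, membrane = as.numeric(mem))
}

# N x (lookback+1) x 6 tensors for forward (old->new up to t) and
# backward (new->old down to t) passes; zero padding beyond the ends
smoother_windows <- function(I, centers, lookback) {
  L <- nrow(I)
  Tn <- lookback + 1L
  gather <- function(offsets) {
    pos <- outer(centers, offsets, `+`)
    inb <- pos >= 1L & pos <= L
    pos_c <- pmin(pmax(pos, 1L), L)
    flat <- I[as.vector(pos_c), , drop = FALSE]
    flat[!as.vector(inb), ] <- 0
    array(flat, dim = c(length(centers), length(offsets), ncol(I)))
  }
  list(Xf = gather(-lookback:0), Xb = gather(lookback:0))
}

#' Train the bidirectional recurrent smoother
#'
#' Trained on full-length fragments (membrane positions included with
#' zero score input); the loss is computed only on labelled, non-membrane
#' residues. Same optimiser and early-stopping contract as [train_cnn()].
#'
#' @param smoother Initialised smoother parameters.
#' @param train_tracks,val_tracks Lists of per-fragment lists with
#'   elements `raw` (CNN score track), `category` (factor) and `labels`
#'   (`D`/`O`/`U`).
#' @param config An [ensemble_config()].
#' @return As [train_cnn()].
#' @export
train_smoother <- function(smoother, train_tracks, val_tracks, config) {
  collect <- function(tracks) {
    Xf <- list(); Xb <- list(); y <- list()
    for (tr in tracks) {
      I <- smoother_input_rows(tr$raw, tr$category)
      keep <- tr$labels %in% c("D", "O") &
        as.character(tr$category) != "MEMBRANE"
      if (!any(keep)) next
      w <- smoother_windows(I, which(keep), config$lookback)
      Xf[[length(Xf) + 1L]] <- w$Xf
      Xb[[length(Xb) + 1L]] <- w$Xb
      y[[length(y) + 1L]] <- as.numeric(tr$labels[keep] == "D")
    }
    abind1 <- function(lst) {
      n <- sum(vapply(lst, function(a) dim(a)[1], integer(1)))
      out <- array(0, dim = c(n, dim(lst[[1]])[2], dim(lst[[1]])[3]))
      at <- 0L
      for (a in lst) {
        out[at + seq_len(dim(a)[1]), , ] <- a
        at <- at + dim(a)[1]
      }
      out
    }
    list(Xf = abind1(Xf), Xb = abind1(Xb), y = unlist(y))
  }
  # cap at fragment level first so the window tensors stay bounded
  precap <- function(tracks, n, seed) {
    sizes <- vapply(tracks, function(tr)
      sum(tr$labels %in% c("D", "O") &
            as.character(tr$category) != "MEMBRANE"), integer(1))
    if (sum(sizes) <= n) return(tracks)
    ord <- with_seed(seed, sample.int(length(tracks)))
    keep <- ord[cumsum(sizes[ord]) <= n]
    tracks[sort(keep)]
  }
  train_tracks <- precap(train_tracks, config$max_smoother_train %||% Inf,
                         config$seed + 2L)
  val_tracks <- precap(val_tracks, config$max_smoother_val %||% Inf,
                       config$seed + 3L)
  tr <- collect(train_tracks)
  va <- collect(val_tracks)
  cap <- function(d, n, seed) {
    if (length(d$y) <= n) return(d)
    keep <- with_seed(seed, sample.int(length(d$y), n))
    list(Xf = d$Xf[keep, , , drop = FALSE],
         Xb = d$Xb[keep, , , drop = FALSE], y = d$y[keep])
  }
  tr <- cap(tr, config$max_smoother_train %||% Inf, config$seed)
  va <- cap(va, config$max_smoother_val %||% Inf, config$seed + 1L)
  if (length(unique(tr$y)) < 2)
    stop("single-class training set for smoother")
  batch_fn <- function(par, b) {
    fw <- rnn_forward(par, tr$Xf[b, , , drop = FALSE],
                      tr$Xb[b, , , drop = FALSE], cache = TRUE)
    rnn_backward(par, fw, tr$Xf[b, , , drop = FALSE],
                 tr$Xb[b, , , drop = FALSE], tr$y[b])
  }
  val_loss_fn <- function(par)
    bce_loss(rnn_forward(par, va$Xf, va$Xb), va$y)
  train_loop(smoother, PARAM_NAMES$rnn, length(tr$y), batch_fn,
             val_loss_fn, config)
}

#' Refined scores from the recurrent smoother
#'
#' @param smoother Trained smoother parameters.
#' @param raw Raw CNN score track (membrane positions 0).
#' @param category Compartment factor for the same residues.
#' @return Refined score track in `[0, 1]`; membrane positions 0.
#' @export
smoother_predict <- function(smoother, raw, category) {
  if (length(raw) != length(category))
    stop("score track and category track differ in length")
  I <- smoother_input_rows(raw, category)
  w <- smoother_windows(I, seq_along(raw), smoother$lookback)
  p <- rnn_forward(smoother, w$Xf, w$Xb)
  p[as.character(category) == "MEMBRANE"] <- 0
  p
}

#' Train the full compartment ensemble on labelled proteins
#'
#' Runs the published pipeline: fragment selection, leakage-guarded
#' split, per-compartment class balancing, feature normalisation, CNN
#' training per compartment, and smoother training on full-length
#' fragments carrying the CNN score tracks.
#'
#' @param proteins List of [annotated_protein()] objects with labels.
#' @param config An [ensemble_config()].
#' @param split_seed Seed of the fragment split.
#' @param quiet Suppress progress messages.
#' @return A trained `compartment_ensemble` with the split, fragments and
#'   training histories attached.
#' @export
train_ensemble <- function(proteins, config = ensemble_config(),
                           split_seed = config$seed, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  frs <- list()
  for (p in proteins)
    frs <- c(frs, select_fragments(p, seed = config$seed))
  assignment <- split_fragments(frs, seed = split_seed)
  by_split <- split(frs, assignment$split)
  say(length(frs), " fragments: ",
      paste(names(by_split), lengths(by_split), collapse = ", "))

  prot_index <- stats::setNames(proteins,
                                vapply(proteins, `[[`, "", "id"))
  rows_cache <- list()
  get_rows <- function(pid) {
    if (is.null(rows_cache[[pid]]))
      rows_cache[[pid]] <<- protein_feature_rows(prot_index[[pid]],
                                                 config$schema)
    rows_cache[[pid]]
  }

  residues <- list(
    train = balance_categories(by_split$train, seed = config$seed),
    validation = balance_categories(by_split$validation,
                                    seed = config$seed + 1L))

  design <- function(tab, stats = NULL, cap = Inf, seed = 0L) {
    if (nrow(tab) > cap)
      tab <- tab[with_seed(seed, sample.int(nrow(tab), cap)), ,
                 drop = FALSE]
    Xs <- list()
    for (pid in unique(tab$parent_id)) {
      rows <- get_rows(pid)
      centers <- tab$pos[tab$parent_id == pid]
      A <- window_stack(rows$R, centers, config$schema)
      Xs[[pid]] <- matrix(A, length(centers), prod(dim(A)[2:3]))
    }
    X <- do.call(rbind, Xs[unique(tab$parent_id)])
    y <- as.numeric(unlist(lapply(unique(tab$parent_id), function(pid)
      tab$label[tab$parent_id == pid])) == "D")
    if (!is.null(stats)) X <- apply_feature_norm(X, stats, config$schema)
    list(X = X, y = y, tab = tab)
  }

  ensemble <- build_ensemble(config)

  # normalisation statistics from a pooled sample of training residues
  pooled <- do.call(rbind, residues$train)
  pool_d <- design(pooled, cap = min(nrow(pooled), 4000L),
                   seed = config$seed)
  ensemble$norm_stats <- feature_norm_stats(pool_d$X, config$schema)

  histories <- list()
  for (cat in names(residues$train)) {
    if (is.null(residues$validation[[cat]])) {
      warning("compartment ", cat, " has no validation residues; skipped")
      next
    }
    tr <- design(residues$train[[cat]], ensemble$norm_stats,
                 cap = config$max_train, seed = config$seed)
    va <- design(residues$validation[[cat]], ensemble$norm_stats,
                 cap = config$max_val, seed = config$seed)
    say("training ", cat, ": ", length(tr$y), " train / ",
        length(va$y), " val residues")
    fit <- with_seed(config$seed + match(cat, CNN_CATEGORIES),
                     train_cnn(ensemble$cnns[[cat]], tr$X, tr$y,
                               va$X, va$y, config))
    ensemble$cnns[[cat]] <- fit$par
    histories[[cat]] <- fit$history
    say("  stopped after ", length(fit$history), " epochs (best ",
        fit$best_epoch, ")")
  }
  ensemble$trained <- TRUE

  raw_cache <- list()
  get_raw <- function(pid) {
    if (is.null(raw_cache[[pid]]))
      raw_cache[[pid]] <<- cnn_predict(ensemble, prot_index[[pid]],
                                       rows = get_rows(pid))
    raw_cache[[pid]]
  }
  fragment_tracks <- function(frags) {
    lapply(frags, function(f) {
      idx <- seq.int(f$start, f$end)
      list(raw = get_raw(f$parent_id)[idx],
           category = get_rows(f$parent_id)$category[idx],
           labels = f$labels)
    })
  }
  say("training smoother on ", length(by_split$train), " fragments")
  sm <- with_seed(config$seed + 7L,
                  train_smoother(ensemble$smoother,
                                 fragment_tracks(by_split$train),
                                 fragment_tracks(by_split$validation),
                                 config))
  ensemble$smoother <- sm$par
  histories$smoother <- sm$history

  ensemble$histories <- histories
  ensemble$split <- assignment
  ensemble$fragments <- frs
  ensemble
}

#' Save / load a trained ensemble artifact
#'
#' The artifact bundles weights, the feature schema (with its hash),
#' normalisation statistics, configuration and seed. [load_model()]
#' refuses artifacts whose stored schema no longer matches its hash.
#'
#' @param model A `compartment_ensemble`.
#' @param path File path for the artifact.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "compartment_ensemble"))
  saveRDS(model, path)
  meta <- list(schema_version = model$schema$version,
               schema_hash = model$schema$hash,
               trained = model$trained,
               seed = model$config$seed,
               cutoff = model$config$cutoff)
  yaml::write_yaml(meta, paste0(path, ".yml"))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "compartment_ensemble"))
    stop("not a compartment ensemble artifact")
  if (!identical(model$schema$hash, schema_hash(model$schema)))
    stop("feature schema hash mismatch: artifact was built with an ",
         "incompatible feature pipeline")
  model
}
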