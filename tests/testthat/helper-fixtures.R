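# Shared fixtures: small labelled proteins built in code and a cached
# miniature trained ensemble for tests that need trained weights.

make_protein <- function(topo, seq = NULL, labels = NULL, id = "p1",
                         rsa = NULL) {
  if (is.null(seq))
    seq <- paste(rep("A", nchar(topo)), collapse = "")
  annotated_protein(id, seq, parse_topology(topo), labels = labels,
                    rsa = rsa)
}

# an ensemble with seeded random weights marked usable for prediction;
# architectural contracts (routing, zeroing, lookback) do not depend on
# training
untrained_usable_ensemble <- function(seed = 1L) {
  cfg <- ensemble_config(seed = seed)
  ens <- build_ensemble(cfg)
  p <- generate_corpus(synthetic_scenario(n_proteins = 3L), seed = seed)[[1]]
  rows <- tmidr:::protein_feature_rows(p, cfg$schema)
  X <- feature_tensor(p$sequence, p$topology,
                      pseudo_profile(p$sequence), p$rsa,
                      seg_mask(p$sequence),
                      centers = which(rows$category != "MEMBRANE"))
  ens$norm_stats <- tmidr:::feature_norm_stats(X, cfg$schema)
  ens$trained <- TRUE
  ens
}

.fixture_env <- new.env()

# miniature trained pipeline, trained once per test session
tiny_trained_model <- function() {
  if (!is.null(.fixture_env$model)) return(.fixture_env$model)
  proteins <- generate_corpus(synthetic_scenario(n_proteins = 30L),
                              seed = 99L)
  cfg <- ensemble_config(max_epochs = 25L, seed = 5L,
                         max_train = 1500L, max_val = 500L,
                         max_smoother_train = 4000L,
                         max_smoother_val = 1000L)
  model <- suppressWarnings(train_ensemble(proteins, cfg, quiet = TRUE))
  .fixture_env$model <- model
  .fixture_env$proteins <- proteins
  model
}

tiny_corpus <- function() {
  tiny_trained_model()
  .fixture_env$proteins
}

protein_by_id <- function(proteins, pid) {
  proteins[[match(pid, vapply(proteins, `[[`, "", "id"))]]
}
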