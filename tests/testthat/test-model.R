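test_that("the ensemble has four seeded compartment models", {
  cfg <- ensemble_config(seed = 3L)
  e1 <- build_ensemble(cfg)
  expect_length(e1$cnns, 4)
  expect_setequal(names(e1$cnns), CNN_CATEGORIES)
  e2 <- build_ensemble(cfg)
  expect_equal(e1$cnns$EXTRA_DISTANT$W1, e2$cnns$EXTRA_DISTANT$W1)
  expect_equal(e1$smoother$Wxf, e2$smoother$Wxf)
  e3 <- build_ensemble(ensemble_config(seed = 4L))
  expect_false(identical(e1$cnns$EXTRA_DISTANT$W1,
                         e3$cnns$EXTRA_DISTANT$W1))
  bad <- feature_schema()
  bad$columns <- bad$columns[1:38]
  expect_error(ensemble_config(schema = bad), "39-column")
})

test_that("network gradients match numerical differentiation", {
  set.seed(71)
  par <- tmidr:::cnn_init(11L, 39L, c(4L, 3L), 3L)
  X <- matrix(rnorm(4 * 429), 4)
  y <- c(0, 1, 1, 0)
  fw <- tmidr:::cnn_forward(par, X, cache = TRUE)
  gr <- tmidr:::cnn_backward(par, fw, y)
  for (nm in c("W1", "W2", "W3", "b2")) {
    eps <- 1e-5
    p1 <- par; p1[[nm]][1] <- p1[[nm]][1] + eps
    p2 <- par; p2[[nm]][1] <- p2[[nm]][1] - eps
    num <- (tmidr:::bce_loss(tmidr:::cnn_forward(p1, X), y) -
              tmidr:::bce_loss(tmidr:::cnn_forward(p2, X), y)) / (2 * eps)
    expect_equal(gr[[nm]][1], num, tolerance = 1e-5)
  }

  pr <- tmidr:::rnn_init(6L, 4L, 12L)
  Xf <- array(rnorm(4 * 13 * 6), c(4, 13, 6))
  Xb <- array(rnorm(4 * 13 * 6), c(4, 13, 6))
  fwr <- tmidr:::rnn_forward(pr, Xf, Xb, cache = TRUE)
  grr <- tmidr:::rnn_backward(pr, fwr, Xf, Xb, y)
  for (nm in c("Wxf", "Whb", "Wo", "bf")) {
    eps <- 1e-5
    p1 <- pr; p1[[nm]][1] <- p1[[nm]][1] + eps
    p2 <- pr; p2[[nm]][1] <- p2[[nm]][1] - eps
    num <- (tmidr:::bce_loss(tmidr:::rnn_forward(p1, Xf, Xb), y) -
              tmidr:::bce_loss(tmidr:::rnn_forward(p2, Xf, Xb), y)) /
      (2 * eps)
    expect_equal(grr[[nm]][1], num, tolerance = 1e-5)
  }
})

test_that("early stopping follows the patience-10 contract", {
  # monotone decrease for 20 epochs then flat: stop at best + 10
  h <- c(seq(1, 0.1, length.out = 20), rep(0.1, 20))
  es <- early_stop_epoch(h, patience = 10)
  expect_equal(es$best_epoch, 20)
  expect_equal(es$stop_epoch, 30)

  # best at epoch 2, patience reached at epoch 12
  h2 <- c(0.5, 0.3, rep(0.4, 30))
  es2 <- early_stop_epoch(h2, patience = 10)
  expect_equal(es2$best_epoch, 2)
  expect_equal(es2$stop_epoch, 12)

  # strictly improving history runs to the end
  h3 <- seq(1, 0.5, length.out = 15)
  es3 <- early_stop_epoch(h3, patience = 10)
  expect_equal(es3$stop_epoch, 15)
  expect_equal(es3$best_epoch, 15)
})

test_that("training restores the best-validation weights", {
  set.seed(73)
  # a separable toy problem per compartment-CNN input shape
  n <- 120
  X <- matrix(rnorm(n * 429), n)
  y <- as.numeric(X[, 1] + X[, 50] > 0)
  idx <- sample(n, 80)
  cfg <- ensemble_config(max_epochs = 30L, seed = 2L)
  fit <- with_seed(2L, train_cnn(tmidr:::cnn_init(11L, 39L, c(4L, 3L), 3L),
                                 X[idx, ], y[idx], X[-idx, ], y[-idx],
                                 cfg))
  final_loss <- tmidr:::bce_loss(
    tmidr:::cnn_forward(fit$par, X[-idx, ]), y[-idx])
  expect_equal(final_loss, min(fit$history), tolerance = 1e-10)
  expect_error(train_cnn(tmidr:::cnn_init(11L, 39L, c(4L, 3L), 3L),
                         X[idx, ], rep(1, 80), X[-idx, ], y[-idx], cfg),
               "single-class")
})

test_that("residues are routed to their own compartment model only", {
  ens <- untrained_usable_ensemble(seed = 9L)
  p <- generate_corpus(synthetic_scenario(n_proteins = 2L), seed = 17L)[[2]]
  cat <- categorize(p$topology)
  raw <- cnn_predict(ens, p)

  expect_true(all(raw >= 0 & raw <= 1))
  expect_true(all(raw[cat == "MEMBRANE"] == 0))

  for (target in CNN_CATEGORIES) {
    if (!any(cat == target)) next
    ablated <- ens
    for (other in setdiff(CNN_CATEGORIES, target)) {
      ablated$cnns[[other]]$W1[] <- 0
      ablated$cnns[[other]]$W3[] <- 0
    }
    raw_abl <- cnn_predict(ablated, p)
    expect_equal(raw_abl[cat == target], raw[cat == target])
    changed <- cat %in% setdiff(CNN_CATEGORIES, target)
    expect_false(isTRUE(all.equal(raw_abl[changed], raw[changed])))
  }

  untr <- build_ensemble(ensemble_config())
  expect_error(cnn_predict(untr, p), "untrained")
})

test_that("the smoother sees exactly 12 steps in each direction", {
  ens <- untrained_usable_ensemble(seed = 13L)
  L <- 60
  cat <- factor(rep("INTRA_DISTANT", L), levels = RESIDUE_CATEGORIES)
  set.seed(74)
  raw <- runif(L)
  base <- smoother_predict(ens$smoother, raw, cat)
  expect_length(base, L)
  expect_true(all(base >= 0 & base <= 1))
  expect_identical(smoother_predict(ens$smoother, raw, cat), base)

  probe <- 30L
  # a perturbation 13 positions away is invisible at the probe
  for (d in c(-13L, 13L, -20L, 20L)) {
    pert <- raw
    pert[probe + d] <- 1 - pert[probe + d]
    expect_equal(smoother_predict(ens$smoother, pert, cat)[probe],
                 base[probe])
  }
  # within the lookback it is visible
  for (d in c(-12L, 12L, -1L, 1L)) {
    pert <- raw
    pert[probe + d] <- 1 - pert[probe + d]
    expect_false(smoother_predict(ens$smoother, pert, cat)[probe] ==
                   base[probe])
  }

  # membrane positions feed zeros and emit zeros
  cat2 <- cat
  cat2[25:35] <- "MEMBRANE"
  I <- tmidr:::smoother_input_rows(raw, cat2)
  expect_true(all(I[25:35, "score"] == 0))
  expect_true(all(smoother_predict(ens$smoother, raw, cat2)[25:35] == 0))

  expect_error(smoother_predict(ens$smoother, raw, cat[1:10]), "length")
})

test_that("model artifacts round-trip and guard their schema", {
  ens <- untrained_usable_ensemble(seed = 21L)
  f <- tempfile(fileext = ".rds")
  save_model(ens, f)
  expect_true(file.exists(paste0(f, ".yml")))
  back <- load_model(f)
  expect_equal(back$cnns$EXTRA_DISTANT$W1, ens$cnns$EXTRA_DISTANT$W1)

  corrupt <- ens
  corrupt$schema$columns[1] <- "tampered"
  f2 <- tempfile(fileext = ".rds")
  saveRDS(corrupt, f2)
  expect_error(load_model(f2), "hash mismatch")
})
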