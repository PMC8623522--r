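test_that("residue metrics match hand arithmetic", {
  m <- residue_metrics(c(TP = 40, FP = 20, TN = 30, FN = 10))
  expect_equal(unname(m["sensitivity"]), 0.8)
  expect_equal(unname(m["specificity"]), 0.6)
  expect_equal(unname(m["balanced_accuracy"]), 0.7)
  expect_equal(unname(m["mcc"]),
               (40 * 30 - 20 * 10) / sqrt(60 * 50 * 50 * 40))

  chance <- residue_metrics(c(TP = 25, FP = 25, TN = 25, FN = 25))
  expect_equal(unname(chance["mcc"]), 0)
  expect_equal(unname(chance["balanced_accuracy"]), 0.5)

  perfect <- residue_metrics(c(TP = 10, FP = 0, TN = 10, FN = 0))
  expect_equal(unname(perfect), c(1, 1, 1, 1))

  # zero denominators surface as NA, not 0
  none_pos <- residue_metrics(c(TP = 0, FP = 5, TN = 5, FN = 0))
  expect_true(is.na(none_pos["sensitivity"]))
  expect_true(is.na(none_pos["balanced_accuracy"]))
  expect_true(is.na(none_pos["mcc"]))
})

test_that("MCC is class-swap symmetric and bounded", {
  set.seed(91)
  for (rep in 1:20) {
    cc <- c(TP = sample(0:30, 1), FP = sample(0:30, 1),
            TN = sample(0:30, 1), FN = sample(0:30, 1))
    swapped <- c(TP = cc[["TN"]], FP = cc[["FN"]],
                 TN = cc[["TP"]], FN = cc[["FP"]])
    m1 <- residue_metrics(cc)[["mcc"]]
    m2 <- residue_metrics(swapped)[["mcc"]]
    if (!is.na(m1)) {
      expect_equal(m1, m2)
      expect_lte(abs(m1), 1)
    }
  }
})

test_that("AUC equals brute-force pair counting", {
  brute_auc <- function(s, y) {
    pos <- s[y]; neg <- s[!y]
    tot <- 0
    for (p in pos) for (n in neg)
      tot <- tot + (p > n) + 0.5 * (p == n)
    tot / (length(pos) * length(neg))
  }
  expect_equal(auc_score(c(0.9, 0.8, 0.2, 0.1),
                         c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auc_score(rep(0.5, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  expect_error(auc_score(1:4, rep(TRUE, 4)), "both classes")

  set.seed(92)
  for (rep in 1:20) {
    n <- sample(4:50, 1)
    s <- round(runif(n), 1)      # coarse grid to exercise ties
    y <- runif(n) < 0.5
    if (!any(y) || all(y)) next
    expect_equal(auc_score(s, y), brute_auc(s, y))
  }
})

test_that("evaluation is restricted to labelled fragment residues", {
  topo <- paste0(strrep("I", 20), strrep("M", 20), strrep("O", 20))
  lab <- c(rep("D", 10), rep("O", 10), rep("O", 20),
           rep("U", 5), rep("O", 15))
  p <- make_protein(topo, labels = lab)
  frag <- tmidr:::new_fragment(p, 1, 60, "idr_with_flanks",
                               categorize(p$topology))
  pred <- data.frame(protein_id = "p1", position = 1:60,
                     call = rep(TRUE, 60))
  ev <- restrict_to_fragments(pred, list(frag))
  # membrane (20) and unobserved (5) residues drop out
  expect_equal(nrow(ev), 35)
  expect_true(all(ev$label %in% c("D", "O")))
  expect_false(any(ev$position %in% 21:40))

  # counts are additive over disjoint fragments
  f1 <- tmidr:::new_fragment(p, 1, 10, "idr_with_flanks",
                             categorize(p$topology))
  f2 <- tmidr:::new_fragment(p, 11, 20, "ordered_random",
                             categorize(p$topology))
  expect_equal(nrow(restrict_to_fragments(pred, list(f1))) +
                 nrow(restrict_to_fragments(pred, list(f2))),
               nrow(restrict_to_fragments(pred, list(f1, f2))))
})

test_that("region detection uses the inclusive 60% threshold", {
  pred <- data.frame(protein_id = "p1", position = 1:10,
                     call_sensitive = c(rep(TRUE, 6), rep(FALSE, 4)))
  reg <- data.frame(protein_id = "p1", start = 1, end = 10)
  rd <- region_detection(reg, pred)
  expect_true(rd$regions$detected[1])
  expect_equal(rd$rate, 1)

  pred5 <- pred
  pred5$call_sensitive <- c(rep(TRUE, 5), rep(FALSE, 5))
  expect_false(region_detection(reg, pred5)$regions$detected[1])

  # monotone: adding disordered calls never un-detects
  set.seed(93)
  for (rep in 1:10) {
    calls <- runif(10) < 0.5
    more <- calls | (runif(10) < 0.3)
    p1 <- pred; p1$call_sensitive <- calls
    p2 <- pred; p2$call_sensitive <- more
    d1 <- region_detection(reg, p1)$regions$detected
    d2 <- region_detection(reg, p2)$regions$detected
    expect_true(!d1 || d2)
  }

  expect_error(region_detection(reg[0, ], pred), "no regions")
})
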