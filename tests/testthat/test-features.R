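test_that("pseudo-profile is a per-residue substitution column", {
  p <- pseudo_profile("AAA")
  expect_equal(dim(p), c(3L, 20L))
  expect_equal(p[1, ], p[2, ])
  expect_equal(p[1, ], p[3, ])

  # each residue's own column is its maximum
  p20 <- pseudo_profile(paste(tmidr:::AA_STANDARD, collapse = ""))
  for (i in 1:20)
    expect_equal(unname(which.max(p20[i, ])), i)

  # unknown residue -> zero row
  px <- pseudo_profile("AXA")
  expect_equal(unname(unclass(px)[2, ]), rep(0, 20))
})

test_that("PSSM files round-trip and mismatches are caught", {
  seq <- "MKTAY"
  prof <- pseudo_profile(seq)
  f <- tempfile()
  write_pssm(prof, seq, f)
  back <- read_pssm(f, sequence = seq)
  expect_equal(unclass(back), unclass(prof), ignore_attr = TRUE)
  expect_equal(attr(back, "source"), "external_pssm")
  expect_error(read_pssm(f, sequence = "MKTAW"), "disagrees")
  expect_error(read_pssm(c("garbage", "lines"), sequence = seq),
               "malformed")
})

test_that("seg mask flags homopolymers and passes diverse sequence", {
  expect_true(all(seg_mask(strrep("A", 15))))
  expect_false(any(seg_mask("ACDEFGHIKLMNPQRSTVWY")))
  # low-complexity prefix, diverse suffix
  m <- seg_mask(paste0(strrep("Q", 20), "ACDEFGHIKLMNPQRSTVWY"))
  expect_true(all(m[1:18]))
  expect_false(any(m[30:40]))
  expect_error(seg_mask("AAA", W = 0), "window width")
})

test_that("seg mask agrees with a brute-force entropy scan", {
  brute_seg <- function(seq, W = 12, K_trig = 2.2, K_ext = 2.5) {
    aa <- strsplit(seq, "")[[1]]
    L <- length(aa)
    w <- min(W, L)
    nwin <- L - w + 1
    K <- vapply(seq_len(nwin), function(i) {
      f <- table(aa[i:(i + w - 1)]) / w
      -sum(f * log2(f))
    }, numeric(1))
    mask <- rep(FALSE, L)
    keep <- rep(FALSE, nwin)
    for (s in which(K <= K_trig)) {
      keep[s] <- TRUE
      i <- s - 1
      while (i >= 1 && K[i] <= K_ext) { keep[i] <- TRUE; i <- i - 1 }
      i <- s + 1
      while (i <= nwin && K[i] <= K_ext) { keep[i] <- TRUE; i <- i + 1 }
    }
    for (i in which(keep)) mask[i:(i + w - 1)] <- TRUE
    mask
  }
  set.seed(31)
  for (rep in 1:15) {
    L <- sample(5:100, 1)
    # mixtures of narrow and wide alphabets to exercise both thresholds
    alpha <- sample(tmidr:::AA_STANDARD, sample(c(2, 3, 20), 1))
    seq <- paste(sample(alpha, L, replace = TRUE), collapse = "")
    expect_identical(seg_mask(seq), brute_seg(seq), label = seq)
  }
})

test_that("protparam descriptors match hand calculations", {
  pp <- protparam_features("GG")
  expect_equal(unname(pp["mw"]),
               2 * tmidr:::AA_RESIDUE_MASS[["G"]] + tmidr:::WATER_MASS)
  # instability of GG: (10/2) * DIWV[G,G]
  expect_equal(unname(pp["instability"]),
               5 * tmidr:::AA_DIWV["G", "G"])

  # acidic windows are acidic
  expect_lt(unname(protparam_features(strrep("D", 8))["pi"]), 4)
  # basic windows are basic
  expect_gt(unname(protparam_features(strrep("K", 8))["pi"]), 9)

  # the pI is a root of the net-charge curve
  for (w in c("ACDEFGHIK", "MNPQRSTVWY", "KKDDEE")) {
    pi <- unname(protparam_features(w)["pi"])
    aa <- strsplit(w, "")[[1]]
    chg <- tmidr:::net_charge(tmidr:::aa_count_matrix(list(aa)), pi)
    expect_lt(abs(chg), 1e-3)
  }
  expect_error(protparam_features(""), "empty")
})

test_that("molecular weight is additive up to one water", {
  mw <- function(s) unname(protparam_features(s)["mw"])
  expect_equal(mw("ACDEF") + mw("GHIKL") - tmidr:::WATER_MASS,
               mw("ACDEFGHIKL"))
})

test_that("per-position protparam track matches the window oracle", {
  seq <- "ACDEFGHIKLMNPQRSTVWYAC"
  tk <- protparam_track(seq, half_width = 5)
  for (i in c(1, 7, 15, 22)) {
    win <- substr(seq, max(1, i - 5), min(nchar(seq), i + 5))
    expect_equal(unname(tk[i, ]), unname(protparam_features(win)),
                 tolerance = 1e-8)
  }
})

test_that("feature schema has 39 stable columns", {
  s1 <- feature_schema()
  s2 <- feature_schema()
  expect_length(s1$columns, 39)
  expect_identical(s1$hash, s2$hash)
  expect_false(identical(s1$hash, feature_schema(half_width = 4)$hash))
})

test_that("window matrices have the declared shape and padding", {
  seq <- "MKLVIIAGFFLLSACDEQPKSQESGGHHRR"
  tr <- parse_topology(paste0(strrep("I", 5), strrep("M", 20),
                              strrep("O", 5)))
  prof <- pseudo_profile(seq)
  rsa <- accessibility_fallback(nchar(seq))
  lc <- seg_mask(seq)

  fm <- build_feature_matrix(seq, tr, prof, rsa, lc, center = 3)
  expect_equal(dim(fm), c(11L, 39L))

  fm1 <- build_feature_matrix(seq, tr, prof, rsa, lc, center = 1)
  expect_equal(unname(fm1[1:5, "valid"]), rep(0, 5))
  expect_equal(unname(rowSums(abs(fm1[1:5, ]))), rep(0, 5))
  expect_equal(unname(fm1[6:11, "valid"]), rep(1, 6))

  # adjacent centres share 10 shifted rows
  fa <- build_feature_matrix(seq, tr, prof, rsa, lc, center = 27)
  fb <- build_feature_matrix(seq, tr, prof, rsa, lc, center = 28)
  expect_equal(fa[2:11, ], fb[1:10, ])

  # membrane centres are not scorable
  expect_error(build_feature_matrix(seq, tr, prof, rsa, lc, center = 10),
               "membrane")

  # the batched tensor agrees with the per-centre builder
  X <- feature_tensor(seq, tr, prof, rsa, lc, centers = c(1, 3, 28))
  expect_equal(dim(X), c(3L, 11L * 39L))
  A <- array(X, dim = c(3, 11, 39))
  expect_equal(A[2, , ], unname(fm))
})

test_that("accessibility input is validated and clamped", {
  f <- tempfile()
  writeLines(c("1\tA\t0.5", "2\tC\t1.4", "3\tD\t-0.2"), f)
  rsa <- read_accessibility(f, 3)
  expect_equal(as.numeric(rsa), c(0.5, 1, 0))
  writeLines(c("1\tA\t0.5"), f)
  expect_error(read_accessibility(f, 3), "incomplete")
})
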