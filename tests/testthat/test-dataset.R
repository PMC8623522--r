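test_that("consensus labelling honours the 90% agreement boundary", {
  # 9/10 tracks missing = exactly 90% -> disordered
  obs <- c(rep(list(TRUE), 9), list(FALSE))
  expect_equal(consensus_labels(obs), "D")
  # 8/10 -> neither side reaches 90%
  obs <- c(rep(list(TRUE), 8), rep(list(FALSE), 2))
  expect_equal(consensus_labels(obs), "U")
  # single track is taken verbatim
  expect_equal(consensus_labels(list(c(TRUE, FALSE, TRUE))),
               c("D", "O", "D"))
  # a 50/50 disagreement is unobserved
  expect_equal(consensus_labels(list(TRUE, FALSE)), "U")
  expect_error(consensus_labels(list()), "no observation")
  expect_error(consensus_labels(list(TRUE, c(TRUE, FALSE))), "length")
})

test_that("consensus labelling is permutation-invariant", {
  set.seed(41)
  obs <- lapply(1:10, function(i) runif(25) < 0.5)
  base <- consensus_labels(obs)
  for (r in 1:5)
    expect_identical(consensus_labels(sample(obs)), base)
})

test_that("IDR fragments carry up to 15 ordered flanking residues", {
  topo <- paste(rep("I", 10), collapse = "")
  topo <- paste0(strrep("I", 40), strrep("M", 20), strrep("O", 40))
  lab <- c(rep("O", 20), rep("D", 5), rep("O", 75))
  p <- make_protein(topo, labels = lab)
  frs <- select_fragments(p, seed = 1)
  idr <- Filter(function(f) f$kind == "idr_with_flanks", frs)
  expect_length(idr, 1)
  expect_equal(idr[[1]]$start, 6)   # 15-residue left flank
  expect_equal(idr[[1]]$end, 40)    # 15-residue right flank
  expect_equal(idr[[1]]$end - idr[[1]]$start + 1, 35)

  # flank truncated at the N-terminus
  lab2 <- c(rep("D", 5), rep("O", 95))
  frs2 <- select_fragments(make_protein(topo, labels = lab2), seed = 1)
  idr2 <- Filter(function(f) f$kind == "idr_with_flanks", frs2)
  expect_equal(idr2[[1]]$start, 1)
  expect_equal(idr2[[1]]$end, 20)

  # flank truncated at unobserved residues
  lab3 <- c(rep("O", 20), "U", rep("O", 5), rep("D", 4), rep("O", 70))
  frs3 <- select_fragments(make_protein(topo, labels = lab3), seed = 1)
  idr3 <- Filter(function(f) f$kind == "idr_with_flanks", frs3)
  expect_equal(idr3[[1]]$start, 22)

  # the maximal disordered run is never cut
  expect_true(all(idr3[[1]]$labels[idr3[[1]]$labels == "D"] == "D"))
})

test_that("fully ordered proteins yield only random ordered fragments", {
  topo <- paste0(strrep("I", 30), strrep("M", 20), strrep("O", 30))
  p <- make_protein(topo, labels = rep("O", 80))
  frs <- select_fragments(p, seed = 3)
  expect_gte(length(frs), 1)
  expect_true(all(vapply(frs, `[[`, "", "kind") == "ordered_random"))
  # and selection is reproducible under the seed
  frs2 <- select_fragments(p, seed = 3)
  expect_identical(vapply(frs, `[[`, "", "id"),
                   vapply(frs2, `[[`, "", "id"))
})

test_that("class balancing respects the 10% tolerance", {
  topo <- paste0("M", strrep("I", 260))
  # 100 disordered, 150 ordered residues, all INTRA_DISTANT
  lab <- c("O", rep("O", 15), rep("D", 100), rep("O", 145))
  p <- make_protein(topo, labels = lab)
  frs <- list(tmidr:::new_fragment(p, 17, 261, "idr_with_flanks",
                                   categorize(p$topology)))
  bal <- suppressWarnings(balance_categories(frs, seed = 1))
  sub <- bal$INTRA_DISTANT
  nd <- sum(sub$label == "D"); no <- sum(sub$label == "O")
  expect_equal(nd, 100)
  expect_lte(no, 110)
  expect_lte(abs(nd - no) / max(nd, no), 0.10)

  # already balanced input is untouched
  lab2 <- c("O", rep("O", 15), rep("D", 50), rep("O", 52), rep("O", 143))
  lab2 <- lab2[1:261]
  p2 <- make_protein(topo, labels = lab2)
  frs2 <- list(tmidr:::new_fragment(p2, 17, 118, "idr_with_flanks",
                                    categorize(p2$topology)))
  bal2 <- suppressWarnings(balance_categories(frs2, seed = 1))
  expect_equal(sum(bal2$INTRA_DISTANT$label == "O"), 52)

  # a compartment with no disordered residues is dropped with a warning
  p3 <- make_protein(topo, labels = rep("O", 261))
  frs3 <- list(tmidr:::new_fragment(p3, 2, 261, "ordered_random",
                                    categorize(p3$topology)))
  warns <- testthat::capture_warnings(
    bal3 <- balance_categories(frs3, seed = 1))
  expect_true(any(grepl("lacks disordered", warns)))
  expect_null(bal3$INTRA_DISTANT)
})

test_that("greedy clustering groups by global identity", {
  cl <- identity_cluster(c("ACDEFGHIKL", "ACDEFGHIKL"))
  expect_length(cl$clusters, 1)
  cl2 <- identity_cluster(c("AAAAAAA", "WWWWWWW"))
  expect_length(cl2$clusters, 2)

  # a pair at exactly the 40% boundary is redundant (inclusive)
  a <- "ACDEFGHIKL"; b <- "ACDEWYPQRS"
  expect_equal(seq_identity(a, b), 0.40)
  cl3 <- identity_cluster(c(a, b), threshold = 0.40)
  expect_length(cl3$clusters, 1)

  # representatives are pairwise below the threshold
  set.seed(51)
  seqs <- vapply(1:12, function(i)
    paste(sample(tmidr:::AA_STANDARD, sample(20:40, 1), replace = TRUE),
          collapse = ""), character(1))
  seqs <- c(seqs, paste0(substr(seqs[1], 1, 30), "AAA"))
  cl4 <- identity_cluster(seqs, threshold = 0.40)
  reps <- cl4$representatives
  for (i in seq_along(reps))
    for (j in seq_len(i - 1L))
      expect_lt(seq_identity(seqs[reps[i]], seqs[reps[j]]), 0.40)
  # membership covers all sequences exactly once
  expect_equal(sort(unname(unlist(cl4$clusters))), seq_along(seqs))
})

test_that("fragment splits are seeded, sized and leakage-guarded", {
  set.seed(61)
  topo <- paste0("M", strrep("I", 60))
  frs <- lapply(1:100, function(i) {
    p <- annotated_protein(
      paste0("p", i),
      paste(sample(tmidr:::AA_STANDARD, 61, replace = TRUE),
            collapse = ""),
      parse_topology(topo), labels = rep("O", 61))
    tmidr:::new_fragment(p, 5, 45, "ordered_random",
                         categorize(p$topology))
  })
  a1 <- split_fragments(frs, seed = 7)
  expect_equal(as.integer(table(a1$split)[c("train", "validation",
                                            "test")]),
               c(70L, 15L, 15L))
  a2 <- split_fragments(frs, seed = 7)
  expect_identical(a1$split, a2$split)

  # plant a near-duplicate pair and check the repair pass
  dup <- frs[[1]]
  dup$parent_id <- "dup"
  dup$id <- "dup:5-45:ordered_random"
  frs_dup <- c(frs, list(dup))
  a3 <- split_fragments(frs_dup, seed = 2, word_filter = 0)
  seqs <- vapply(frs_dup, `[[`, "", "sequence")
  test_i <- which(a3$split == "test")
  other_i <- which(a3$split != "test")
  for (i in test_i)
    for (j in other_i)
      expect_lt(seq_identity(seqs[i], seqs[j]), 0.40)

  # fully redundant input cannot satisfy the guard
  same <- lapply(1:6, function(i) {
    f <- frs[[1]]
    f$id <- paste0("c", i)
    f
  })
  expect_error(split_fragments(same, seed = 1), "mutually redundant")
})
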