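# Sliding Fisher-Irwin comparison, decoy Z calibration, distance transform,
# UPGMA clustering and benchmark success.

test_that("reverse complement swaps strands and reverses columns", {
  m <- word_pwm("TTAATGTGT")
  rc <- reverse_complement_pwm(m)
  expect_identical(pwm_consensus(rc), "ACACATTAA")
  expect_equal(unclass(reverse_complement_pwm(rc)), unclass(m),
               ignore_attr = TRUE)
  uni <- pwm(matrix(0.25, 4, 5))
  expect_equal(unclass(reverse_complement_pwm(uni)), unclass(uni),
               ignore_attr = TRUE)
})

test_that("the Fisher-Irwin p-value matches the printed worked example", {
  expect_equal(fisher_irwin_p(6, 8), 849 / 12870, tolerance = 1e-12)
  expect_equal(849 / 12870, 0.0660, tolerance = 1e-3)
})

test_that("self-comparison wins at offset zero on the forward strand", {
  m <- soft_word_pwm("ACGTTGCA")
  r <- fisher_slide_compare(m, m)
  expect_equal(r$offset, 0L)
  expect_identical(r$strand, "+")
  expect_equal(r$overlap, 8L)
  expect_equal(r$matches, 8L)
  # comparing with the reverse complement gives the same best p on -
  rrc <- fisher_slide_compare(m, reverse_complement_pwm(m))
  expect_identical(rrc$strand, "-")
  expect_equal(rrc$p_value, r$p_value, tolerance = 1e-12)
  expect_error(fisher_slide_compare(m, pwm(matrix(c(1, 0, 0, 0), 4, 1))),
               "at least")
})

test_that("best p is symmetric for equal-length motifs", {
  pwms <- make_random_pwms(6, 8, seed = 101)
  for (i in 1:3) {
    a <- pwms[[2 * i - 1]]; b <- pwms[[2 * i]]
    expect_equal(fisher_slide_compare(a, b)$p_value,
                 fisher_slide_compare(b, a)$p_value, tolerance = 1e-12)
  }
})

test_that("decoy sets drop redundant motifs and keep dissimilar ones", {
  m <- soft_word_pwm("ACGTACGT")
  kept <- build_decoy_set(list(m, m, soft_word_pwm("GGTTGGAA")))
  expect_length(kept, 2L)
  rand <- make_random_pwms(12, 8, seed = 103)
  ds <- build_decoy_set(rand)
  # audit: every retained pair is mutually non-redundant
  prm <- comparison_params()
  for (i in seq_along(ds)) for (j in seq_along(ds)) {
    if (i >= j) next
    expect_gte(fisher_slide_compare(ds[[i]], ds[[j]])$p_value,
               prm$decoy_redundancy_p)
  }
  expect_error(build_decoy_set(list()), "at least 2")
})

test_that("Z-scores calibrate against decoys, cap at 10 and detect self-similarity", {
  prm <- comparison_params()
  decoys <- build_decoy_set(make_random_pwms(30, 9, seed = 107))
  q <- soft_word_pwm("TTAATGTGT", p = 0.97)
  self_cmp <- fisher_slide_compare(q, q, prm)
  z_self <- similarity_zscore(self_cmp, q, decoys, prm)
  expect_gt(z_self, prm$z_success)
  expect_lte(z_self, prm$z_cap)
  # a raw Z beyond the cap is reported as the cap
  tiny <- self_cmp
  tiny$p_value <- 1e-30
  expect_equal(similarity_zscore(tiny, q, decoys, prm), prm$z_cap)
  # query at the decoy mean gives z = 0: synthesize via the definition
  x_dec <- vapply(decoys, function(d)
    -log10(fisher_slide_compare(q, d, prm)$p_value), numeric(1))
  fake <- self_cmp
  fake$p_value <- 10^(-mean(x_dec))
  expect_equal(similarity_zscore(fake, q, decoys, prm), 0, tolerance = 1e-9)
  # z is monotone decreasing in the query-target p-value
  worse <- self_cmp; worse$p_value <- min(1, self_cmp$p_value * 100)
  expect_lte(similarity_zscore(worse, q, decoys, prm), z_self)
})

test_that("the Z-to-distance transform matches its closed form", {
  prm <- comparison_params()
  expect_equal(z_to_distance(10, prm), 0)
  expect_equal(z_to_distance(2, prm), 8 / 11.1, tolerance = 1e-12)
  expect_equal(z_to_distance(2, prm), 0.7207, tolerance = 1e-3)
  expect_equal(z_to_distance(-1.1, prm), 1.0, tolerance = 1e-12)
  z <- seq(-1.1, 10, by = 0.1)
  d <- z_to_distance(z, prm)
  expect_true(all(d >= 0 & d <= 1 + 1e-12))
  expect_true(all(diff(d) < 0))
  expect_error(z_to_distance(11, prm), "cap")
})

test_that("UPGMA reproduces the hand-worked three-leaf tree", {
  D <- matrix(c(0, 0.2, 0.6, 0.2, 0, 0.6, 0.6, 0.6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma_tree(D)
  expect_equal(sort(tr$hclust$height), c(0.2, 0.6), tolerance = 1e-12)
  # ultrametric phylo: A and B join at height 0.1, C at 0.3
  ph <- tr$phylo
  depths <- ape::node.depth.edgelength(ph)
  tip_depth <- max(depths[seq_along(ph$tip.label)])
  expect_equal(tip_depth, 0.3, tolerance = 1e-12)
  coph <- ape::cophenetic.phylo(ph)
  expect_equal(coph["A", "B"], 0.2, tolerance = 1e-12)
  expect_equal(coph["A", "C"], 0.6, tolerance = 1e-12)
  # two leaves join at half the distance
  D2 <- matrix(c(0, 0.5, 0.5, 0), 2, 2, dimnames = list(c("x", "y"),
                                                        c("x", "y")))
  tr2 <- upgma_tree(D2)
  expect_equal(max(ape::node.depth.edgelength(tr2$phylo)), 0.25,
               tolerance = 1e-12)
  # invalid matrices are rejected
  bad <- D; bad[1, 2] <- 0.9
  expect_error(upgma_tree(bad), "symmetric")
  nan <- D; nan[1, 3] <- NaN; nan[3, 1] <- NaN
  expect_error(upgma_tree(nan), "non-finite")
})

test_that("UPGMA agrees with an independent naive implementation", {
  set.seed(109)
  for (rep in 1:10) {
    n <- 8
    D <- matrix(0, n, n)
    D[upper.tri(D)] <- runif(n * (n - 1) / 2, 0.05, 1)
    D <- D + t(D)
    labels <- paste0("m", 1:n)
    dimnames(D) <- list(labels, labels)
    tr <- upgma_tree(D)
    got <- as.matrix(stats::cophenetic(tr$hclust))[labels, labels]
    want <- oracle_upgma_cophenetic(D)
    dimnames(want) <- dimnames(D)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("cluster cutting recovers planted motif families", {
  prm <- comparison_params()
  # all pairwise z above the success cutoff -> one cluster
  n <- 4
  D1 <- matrix(z_to_distance(5, prm), n, n); diag(D1) <- 0
  expect_equal(unname(max(cut_clusters(upgma_tree(D1,
                                                  paste0("m", 1:n)), prm))), 1L)
  # all pairwise z below zero -> all singletons
  D2 <- matrix(z_to_distance(-1, prm), n, n); diag(D2) <- 0
  expect_equal(unname(max(cut_clusters(upgma_tree(D2,
                                                  paste0("m", 1:n)), prm))), n)
  # two planted families separate cleanly
  fam1 <- lapply(1:3, function(i) soft_word_pwm("AAGGAAGG", p = 0.9 - 0.01 * i,
                                                name = paste0("f1_", i)))
  fam2 <- lapply(1:3, function(i) soft_word_pwm("CTCTTCTC", p = 0.9 - 0.01 * i,
                                                name = paste0("f2_", i)))
  motifs <- c(fam1, fam2)
  decoys <- build_decoy_set(make_random_pwms(40, 8, seed = 113))
  nm <- length(motifs)
  Z <- matrix(prm$z_cap, nm, nm)
  for (i in seq_len(nm)) for (j in seq_len(nm)) {
    if (i == j) next
    cmp <- fisher_slide_compare(motifs[[i]], motifs[[j]], prm)
    Z[i, j] <- similarity_zscore(cmp, motifs[[i]], decoys, prm)
  }
  Z <- pmin(Z, t(Z))   # symmetrize conservatively
  D <- z_to_distance(Z, prm); diag(D) <- 0
  cl <- cut_clusters(upgma_tree(D, vapply(motifs, attr, "", "name")), prm)
  expect_equal(length(unique(cl)), 2L)
  expect_length(unique(cl[1:3]), 1L)
  expect_length(unique(cl[4:6]), 1L)
})

test_that("benchmark success counts calibrated matches", {
  prm <- comparison_params()
  decoys <- build_decoy_set(make_random_pwms(30, 8, seed = 127))
  preds <- lapply(c("ACGTACGT", "GGGTTTAA"), soft_word_pwm, p = 0.95)
  pairs <- lapply(preds, function(m) list(m, m))
  s <- benchmark_success(pairs, decoys, prm)
  expect_equal(as.numeric(s), 1.0)
  expect_true(all(attr(s, "z") >= prm$z_success))
  expect_error(benchmark_success(list(), decoys, prm), "no motif pairs")
})
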