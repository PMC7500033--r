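ref <- bundled_ref()

freqs_from <- function(ls5, hs5, x_i, sample_id = "s") {
  sp <- deletion_span(ls5, hs5, ls5 > hs5)
  len <- span_length(sp, ref)
  cat_ <- structure(list(
    calls = data.frame(ls5 = sp$ls5, hs5 = sp$hs5, length = len,
                       x_i = as.integer(x_i), wraps = sp$wraps,
                       possible_insertion = len > 15000L),
    depth = rep(100L, ref$length), r_t = 1000000L, L_r = 150,
    sample_id = sample_id, min_anchor = NULL),
    class = "deletion_catalog")
  frequencies(cat_, ref)
}

# a pattern_matrix built directly from binned weights, for clustering/PCA
pm_from_bins <- function(cells, id) {
  bins <- matrix(0, 80, 80)
  for (cl in cells) bins[cl[1], cl[2]] <- cl[3]
  structure(list(bins = bins / sum(bins), sample_id = id,
                 excluded_mass = 0), class = "pattern_matrix")
}

test_that("breakpoint binning applies the published exclusions", {
  fr <- freqs_from(c(8471, 1000, 3200, 2000), c(13447, 1030, 13000, 16000),
                   c(10, 20, 5, 5))
  pm <- bin_breakpoints(fr, ref)
  # the 31-bp span (< 40) and the T-region spans are excluded:
  # (3200, 13000) matches the second zone; (2000, 16000) the first
  expect_equal(sum(pm$bins), 1)
  expect_equal(pm$bins[(8471 - 1) %/% 207 + 1, (13447 - 1) %/% 207 + 1], 1)
  expect_equal(pm$excluded_mass, 30 / 40)
  # single surviving breakpoint: one cell carries everything
  expect_identical(sum(pm$bins > 0), 1L)
  # nothing survives: all-zero matrix with a warning
  expect_warning(pm0 <- bin_breakpoints(freqs_from(100, 120, 5), ref),
                 "no breakpoints")
  expect_equal(sum(pm0$bins), 0)
})

test_that("complete-linkage clustering separates synthetic pattern groups", {
  mk_group <- function(center, ids, seed) {
    withr::with_seed(seed, lapply(ids, function(id) {
      cells <- lapply(seq_len(20), function(i)
        c(min(80, center[1] + sample(0:2, 1)),
          min(80, center[2] + sample(0:2, 1)), 1))
      pm_from_bins(cells, id)
    }))
  }
  g1 <- mk_group(c(5, 70), paste0("uniform", 1:3), 1)
  g2 <- mk_group(c(25, 70), paste0("fountain", 1:3), 2)
  g3 <- mk_group(c(10, 20), paste0("minor", 1:3), 3)
  cl <- cluster_samples(c(g1, g2, g3))
  k3 <- cutree(cl$hclust, k = 3)
  expect_identical(length(unique(k3[paste0("uniform", 1:3)])), 1L)
  expect_identical(length(unique(k3[paste0("fountain", 1:3)])), 1L)
  expect_identical(length(unique(k3[paste0("minor", 1:3)])), 1L)
  expect_identical(length(unique(k3)), 3L)
  # permuting input order leaves the tree invariant (samples are sorted)
  cl2 <- cluster_samples(c(g3, g1, g2)[c(2, 5, 1, 9, 3, 7, 4, 6, 8)])
  expect_identical(cl$newick, cl2$newick)
  # identical matrices merge at height zero
  cl3 <- cluster_samples(list(g1[[1]],
                              structure(c(g1[[1]][names(g1[[1]]) != "sample_id"],
                                          sample_id = "copy"),
                                        class = "pattern_matrix")))
  expect_equal(cl3$merge_heights[1], 0)
  expect_error(cluster_samples(g1[1]), "at least 2")
})

test_that("PCA isolates a constructed single-bin contrast", {
  base <- list(c(10, 60, 1), c(30, 55, 1))
  mats <- c(
    lapply(1:3, function(i) pm_from_bins(c(base, list(c(50, 70, 0.02 * i))),
                                         paste0("a", i))),
    lapply(1:3, function(i) pm_from_bins(c(base, list(c(50, 70, 1 + 0.02 * i))),
                                         paste0("b", i))))
  pc <- pca_patterns(mats, n_components = 2)
  w1 <- abs(pc$weights[[1]])
  # the contrastive bin and its compensating co-bins dominate component 1
  expect_identical(which(w1 == max(w1)), which(abs(pc$weights[[1]]) ==
                                               max(w1)))
  top <- order(w1, decreasing = TRUE)[1:3]
  expect_true((50 + (70 - 1) * 80) %in% top)
  # scores are centered: column means are zero
  expect_true(all(abs(colMeans(pc$scores)) < 1e-12))
  # component vectors have unit norm
  expect_equal(sum(pc$weights[[1]]^2), 1)
  expect_error(pca_patterns(mats[1:2], n_components = 2), "at least")
  same <- lapply(1:4, function(i) pm_from_bins(base, paste0("s", i)))
  expect_error(pca_patterns(same, 3), "zero-variance")
})

test_that("length spectra conserve mass across bin widths", {
  fr <- freqs_from(c(8471, 1000, 2000), c(13447, 1500, 2100), c(10, 5, 2))
  s1 <- length_spectrum(fr, bin_bp = 1L)
  s400 <- length_spectrum(fr, bin_bp = 400L)
  expect_equal(sum(s1$freq), sum(fr$table$f_i_bg))
  expect_equal(sum(s1$freq), sum(s400$freq))
  expect_equal(s1$freq[4977], fr$table$f_i_bg[1])
  # > 15 kbp tail flagged as possible insertions
  frx <- freqs_from(c(16400, 300), c(15971, 400), c(2, 5))
  sx <- length_spectrum(frx)
  expect_equal(sx$possible_insertion_mass,
               frx$table$f_i_bg[frx$table$length > 15000])
})

test_that("terminus histograms split LS5'/HS5' mass and honor TMH cuts", {
  fr <- freqs_from(c(8471, 2000), c(13447, 6000), c(10, 5))
  ann <- annotate_context(fr$table, ref)
  th <- terminus_histogram(fr, ann, tmh_max = Inf)
  expect_equal(sum(th$ls5_freq), sum(fr$table$f_i_bg))
  expect_equal(sum(th$hs5_freq), sum(fr$table$f_i_bg))
  expect_equal(th$ls5_freq[(8471 - 1) %/% 250 + 1] +
               th$ls5_freq[(2000 - 1) %/% 250 + 1], sum(fr$table$f_i_bg))
  # excluding TMH >= 10 removes the common deletion (TMH 13)
  th2 <- terminus_histogram(fr, ann, tmh_max = 9L)
  expect_equal(sum(th2$ls5_freq), fr$table$f_i_bg[fr$table$ls5 == 2000])
  # all deletions excluded: empty histogram
  th3 <- terminus_histogram(fr, ann, tmh_max = -1L)
  expect_equal(sum(th3$ls5_freq) + sum(th3$hs5_freq), 0)
})
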