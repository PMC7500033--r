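ref <- bundled_ref()
fmap <- bundled_fmap()

manual_catalog <- function(ls5, hs5, x_i, r_t, L_r, depth = NULL,
                           wraps = NULL) {
  if (is.null(wraps)) wraps <- ls5 > hs5
  sp <- deletion_span(ls5, hs5, wraps)
  len <- span_length(sp, ref)
  structure(list(
    calls = data.frame(ls5 = sp$ls5, hs5 = sp$hs5, length = len,
                       x_i = as.integer(x_i), wraps = sp$wraps,
                       possible_insertion = len > 15000L),
    depth = if (is.null(depth)) rep(100L, ref$length) else depth,
    r_t = as.integer(r_t), L_r = L_r, sample_id = "manual",
    min_anchor = NULL), class = "deletion_catalog")
}

test_that("mappability factors follow median-over-junction-depth", {
  sp <- deletion_span(c(1000, 4000), c(2000, 6000))
  uni <- rep(100, ref$length)
  expect_equal(mappability_factor(uni, sp)$delta_i, c(1, 1))
  dip <- uni; dip[c(1000, 2000)] <- 50
  expect_equal(mappability_factor(dip, sp[1, ])$delta_i, 2)
  asym <- uni; asym[4000] <- 80; asym[6000] <- 120
  expect_equal(mappability_factor(asym, sp[2, ])$delta_i, 1)
  # zero depth at both junction positions: capped and flagged
  z <- uni; z[c(1000, 2000)] <- 0
  mf <- mappability_factor(z, sp[1, ])
  expect_true(mf$low_mappability)
  expect_equal(mf$delta_i, 10)
  expect_error(mappability_factor(rep(0, ref$length), sp), "median")
})

test_that("the frequency formula matches hand substitution", {
  # single deletion: L_u = 16571, span 4977 (L_i = 11594), delta = 1,
  # x = 10, L_r = 150, r_t = 1e5:
  # f = 16571*10 / (150*1e5 - 11594*10 + 16571*10) = 165710/15049770
  cat_ <- manual_catalog(8471, 13447, 10, 1e5, 150)
  fr <- frequencies(cat_, ref)
  expect_equal(fr$table$f_i, 165710 / 15049770, tolerance = 1e-12)
  expect_equal(fr$table$f_i_bound, 165710 / 15000000, tolerance = 1e-12)
  expect_equal(fr$f_u, 1 - fr$table$f_i)
  # no deletions
  fr0 <- frequencies(manual_catalog(integer(), integer(), integer(),
                                    1000, 150), ref)
  expect_identical(nrow(fr0$table), 0L)
  expect_equal(fr0$f_u, 1)
  expect_error(frequencies(manual_catalog(8471, 13447, 10, 0, 150), ref),
               "no mapped reads")
})

test_that("every frequency respects the upper-bound approximation", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      n <- sample(1:15, 1)
      ls5 <- sample(100:12000, n)
      len <- sample(10:4000, n, replace = TRUE)
      cat_ <- manual_catalog(ls5, pmin(ls5 + len, 16571L),
                             sample(1:500, n, replace = TRUE),
                             r_t = 5e5, L_r = 150)
      fr <- frequencies(cat_, ref)
      expect_true(all(fr$table$f_i <= fr$table$f_i_bound + 1e-12))
      expect_true(all(fr$table$f_i >= 0 & fr$table$f_i <= 1))
      expect_equal(fr$f_u + sum(fr$table$f_i), 1, tolerance = 1e-9)
    }
  })
})

test_that("background subtraction floors at zero per exact junction", {
  cat_ <- manual_catalog(c(1000, 3000), c(2000, 3500), c(5, 5), 1e5, 150)
  fr <- frequencies(cat_, ref)
  ctl <- fr
  ctl$table$f_i <- c(fr$table$f_i[1] / 10, fr$table$f_i[2] * 2)
  out <- subtract_background(fr, ctl)
  expect_equal(out$table$f_i_bg[1], fr$table$f_i[1] - ctl$table$f_i[1])
  expect_equal(out$table$f_i_bg[2], 0)     # control exceeds sample: floor
  # junction absent from control subtracts nothing; empty control list
  ctl2 <- ctl; ctl2$table <- ctl$table[1, ]
  out2 <- subtract_background(fr, ctl2)
  expect_equal(out2$table$f_i_bg[2], fr$table$f_i[2])
  expect_identical(subtract_background(fr, list())$table$f_i_bg,
                   fr$table$f_i)
  # mean over several controls
  out3 <- subtract_background(fr, list(ctl2, fr))
  expect_equal(out3$table$f_i_bg[1],
               max(0, fr$table$f_i[1] -
                     mean(c(ctl2$table$f_i[1], fr$table$f_i[1]))))
})

test_that("ablation equals frequency-weighted fractional loss", {
  cat_ <- manual_catalog(8471, 13447, 10, 1e5, 150)
  fr <- frequencies(cat_, ref)
  fr$table$f_i_bg <- 0.01
  expect_equal(ablation_at_biopsy(fr), 0.01 * 4977 / 16571)
  fr$table$f_i_bg <- 0
  expect_equal(ablation_at_biopsy(fr), 0)
  # limit case: one species deleting all but one base
  cat2 <- manual_catalog(2, 16571, 1, 1e6, 150)
  fr2 <- frequencies(cat2, ref, anchor_correction = FALSE)
  fr2$table$f_i_bg <- 1
  expect_equal(ablation_at_biopsy(fr2), (16571 - 1) / 16571)
})

test_that("ablation projects linearly back to onset age", {
  expect_equal(ablation_at_onset(0.10, 30, 60), 0.05)
  expect_equal(ablation_at_onset(0.07, 45, 45), 0.07)
  expect_equal(ablation_at_onset(0.023, 35, 62), 0.023 * 35 / 62)
  expect_error(ablation_at_onset(0.1, 70, 60), "y_onset")
  expect_error(ablation_at_onset(0.1, 10, 0), "y_biopsy")
})

test_that("remaining-fraction profile is consistent with ablation", {
  cat_ <- manual_catalog(c(8471, 16500), c(13447, 100), c(10, 4), 1e5, 150)
  fr <- frequencies(cat_, ref)
  prof <- remaining_fraction_profile(fr)
  expect_equal(prof[9000], 1 - fr$table$f_i_bg[1])
  expect_equal(prof[50], 1 - fr$table$f_i_bg[2])    # wrapped deletion
  expect_equal(prof[15000], 1)
  expect_true(all(prof >= 0 & prof <= 1))
  # area above the curve equals ablation, to numerical identity
  expect_equal(mean(1 - prof), ablation_at_biopsy(fr), tolerance = 1e-9)
})

test_that("ablation is invariant to row order and row splitting", {
  cat1 <- manual_catalog(c(1000, 6000), c(2000, 9000), c(8, 6), 1e5, 150)
  cat2 <- manual_catalog(c(6000, 1000), c(9000, 2000), c(6, 8), 1e5, 150)
  cat3 <- manual_catalog(c(1000, 6000, 6000), c(2000, 9000, 9000),
                         c(8, 3, 3), 1e5, 150)
  a <- function(x) ablation_at_biopsy(frequencies(x, ref))
  expect_equal(a(cat1), a(cat2))
  expect_equal(a(cat1), a(cat3))
})

test_that("feature ablation combines multiplicatively", {
  cat_ <- manual_catalog(c(6000, 9300), c(7500, 10100), c(10, 10), 1e5, 150)
  fr <- frequencies(cat_, ref)
  fr$table$f_i_bg <- c(0.1, 0.1)
  fa <- feature_ablation(fr, fmap,
                         list(cox1 = "CO1", cox3 = "CO3"), combine = TRUE)
  expect_equal(unname(fa$per_set), c(0.1, 0.1))
  expect_equal(fa$combined, 1 - 0.81)
  # a deletion covering no base of the set contributes nothing
  fa2 <- feature_ablation(fr, fmap, list(nd1 = "ND1"))
  expect_equal(unname(fa2$per_set), 0)
  # a whole-genome set captures the total deletion mass
  fa3 <- feature_ablation(fr, fmap, list(all = c("minor_arc", "major_arc",
                                                 "oriL", "7S_3prime")))
  expect_equal(unname(fa3$per_set), 0.2)
  expect_error(feature_ablation(fr, fmap, list(a = "NOPE")), "unknown")
})

test_that("muscle-sample geometry reproduces the multi-fiber chain", {
  b20 <- multi_fiber_boundaries(20, 1.06, 3630, nuclei_total = 380100)
  expect_equal(b20$volume_uL, 18.87, tolerance = 0.005)
  expect_equal(b20$face_area_mm2, 7.09, tolerance = 0.005)
  expect_equal(b20$fibers, 1950, tolerance = 0.01)
  expect_equal(b20$boundary_frequency, 5.12e-4, tolerance = 0.01)
  b25 <- multi_fiber_boundaries(25, 1.06, 3630, nuclei_total = 380100,
                                mtdna_total = 1.08e9)
  expect_equal(b25$nuclei_per_fiber, 168, tolerance = 0.01)
  expect_equal(b25$single_copy_frequency, 1 / 1.08e9)
  # scaling law: doubling fiber area halves the count, doubles the bound
  b2 <- multi_fiber_boundaries(20, 1.06, 2 * 3630)
  expect_equal(b2$fibers, b20$fibers / 2)
  expect_equal(b2$boundary_frequency, 2 * b20$boundary_frequency)
})
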