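test_that("simulation is reproducible and conserves candidates", {
  cfg <- sim_config(6, params = list(sel = 0.3, mu = 8000, sigma = 2500,
                                     shape = 900),
                    n_per_direction = 5000, seed = 3)
  s1 <- simulate_deletions(cfg)
  s2 <- simulate_deletions(cfg)
  expect_identical(s1$deletions, s2$deletions)
  expect_identical(s1$histogram, s2$histogram)
  expect_identical(s1$attempts, s1$accepted_raw + sum(s1$rejections))
  expect_true(all(table(s1$deletions$direction) == 5000))
  # models 3 and 4 are single-direction
  s3 <- simulate_deletions(sim_config(3, n_per_direction = 2000, seed = 1))
  expect_identical(unique(s3$deletions$direction), "cw")
})

test_that("model 1 with full selection survival is uniform", {
  cfg <- sim_config(1, params = list(sel = 1), n_per_direction = 50000,
                    seed = 2)
  s <- simulate_deletions(cfg)
  expect_identical(sum(s$rejections), 0L)
  ks <- suppressWarnings(
    ks.test(s$deletions$ls5, "punif", 1, cfg$L))
  expect_gt(ks$p.value, 0.01)
})

test_that("the selection coefficient has survival semantics", {
  base <- list(mu = 12000, sigma = 1500, shape = 500)
  # sel = 0: every candidate covering the selected-against origin dies
  s0 <- simulate_deletions(sim_config(3, params = c(base, sel = 0),
                                      n_per_direction = 3000, seed = 4))
  cover_oriL <- ((5780 - s0$deletions$ls5) %% 16571) <
    s0$deletions$len
  expect_identical(sum(cover_oriL), 0L)
  # sel = 0.5: survival of origin-covering candidates is binomial
  cfg5 <- sim_config(3, params = c(base, sel = 0.5),
                     n_per_direction = 20000, seed = 5)
  withr::with_seed(5, {
    cand <- draw_deletion(cfg5, "cw", 50000)
    fl <- filter_candidates(cand, cfg5, "cw")
  })
  kept <- sum(((5780 - fl$accepted$ls5) %% 16571) < fl$accepted$len)
  dropped <- unname(fl$rejections["origin_selection"])
  p_hat <- kept / (kept + dropped)
  se <- sqrt(0.25 / (kept + dropped))
  expect_lt(abs(p_hat - 0.5), 3 * se)
  # sel = 1 admits every origin-covering candidate
  cfg1 <- sim_config(3, params = c(base, sel = 1),
                     n_per_direction = 1000, seed = 5)
  withr::with_seed(5, {
    fl1 <- filter_candidates(draw_deletion(cfg1, "cw", 20000), cfg1, "cw")
  })
  expect_identical(unname(fl1$rejections["origin_selection"]), 0L)
})

test_that("mean accepted length increases with mu", {
  means <- vapply(c(4000, 7000, 10000), function(mu) {
    s <- simulate_deletions(sim_config(6, params = list(sel = 0.3, mu = mu,
                                                        sigma = 1200,
                                                        shape = 800),
                                       n_per_direction = 4000, seed = 6))
    mean(s$deletions$len)
  }, 0.0)
  expect_true(all(diff(means) > 0))
})

test_that("strand-displacement geometry yields the double bowtie", {
  cfg <- sim_config(6, params = list(sel = 0.1, mu = 9000, sigma = 3000,
                                     shape = 800),
                    n_per_direction = 20000, seed = 7)
  s <- simulate_deletions(cfg)
  h <- s$histogram
  oriL_bin <- (5780 - 1) %/% 250 + 1
  s7_bin <- (16070 - 1) %/% 250 + 1
  # LS5' termini fall off into the major arc from oriL; HS5' termini
  # fall off from the 7S-3' terminus
  expect_equal(which.max(h$ls5_freq), oriL_bin)
  expect_equal(which.max(h$hs5_freq), s7_bin - 1)
  ls_tail <- h$ls5_freq[(oriL_bin + 2):(oriL_bin + 14)]
  expect_lt(mean(diff(ls_tail)), 0)        # monotone-in-trend falloff
  hs_tail <- rev(h$hs5_freq[(s7_bin - 14):(s7_bin - 3)])
  expect_lt(mean(diff(hs_tail)), 0)
})

test_that("pathological parameters abort with a diagnostic", {
  cfg <- sim_config(3, params = list(sel = 0, mu = 16000, sigma = 10,
                                     shape = 10),
                    n_per_direction = 1000, seed = 8)
  expect_error(simulate_deletions(cfg), "acceptance rate")
})

test_that("fitting a model to its own output approaches self-consistency", {
  truth <- list(sel = 0.4, mu = 8000, sigma = 2000, shape = 700)
  data <- simulate_deletions(sim_config(6, params = truth,
                                        n_per_direction = 60000, seed = 9))
  fit <- suppressWarnings(
    fit_model(data$histogram, 6, seed = 10, n_per_direction = 12000,
              maxit = 80))
  expect_gt(fit$r2, 0.95)
  expect_lt(abs(fit$params$mu - truth$mu) / truth$mu, 0.25)
})
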