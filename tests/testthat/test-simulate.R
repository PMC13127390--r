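identity_config <- function(n = 50, r = 5) {
  sim_config(n_cases = n, n_raters = r, prevalence = c(0.3, 0.3, 0.2, 0.2),
             template = diag(4), schema = her2_schema())
}

test_that("identity confusion gives perfect agreement on every metric", {
  m <- simulate_panel(identity_config(), seed = 1)
  expect_equal(opa(m)$estimate, 1)
  expect_equal(fleiss_kappa(m)$estimate, 1, tolerance = 1e-12)
  expect_equal(icc_a1(m)$estimate, 1, tolerance = 1e-12)
  # scores equal the hidden truth for every rater
  expect_true(all(as.matrix(m, labels = TRUE) == attr(m, "truth")))
})

test_that("degenerate prevalence routes every draw through one confusion row", {
  conf <- rbind(c(0.5, 0.5, 0, 0), c(1, 0, 0, 0), c(1, 0, 0, 0), c(1, 0, 0, 0))
  cfg <- sim_config(n_cases = 300, n_raters = 3, prevalence = c(1, 0, 0, 0),
                    template = conf)
  m <- simulate_panel(cfg, seed = 2)
  expect_true(all(attr(m, "truth") == "0"))
  expect_true(all(m$scores %in% 0:1))
  expect_equal(mean(m$scores == 1L), 0.5, tolerance = 0.05)
})

test_that("simulation is seed-deterministic end to end", {
  cfg <- her2_default_config(n_cases = 80)
  a <- simulate_panel(cfg, seed = 5)
  b <- simulate_panel(cfg, seed = 5)
  expect_identical(a$scores, b$scores)
  expect_identical(attr(a, "truth"), attr(b, "truth"))
  expect_identical(a$case_meta, b$case_meta)
  expect_false(identical(simulate_panel(cfg, seed = 6)$scores, a$scores))
})

test_that("simulated OPA converges to the closed-form unanimity probability", {
  # uniform confusion rows: unanimity probability is C * (1/C)^R exactly
  C <- 2; R <- 4
  cfg <- sim_config(n_cases = 20000, n_raters = R, prevalence = c(0.5, 0.5),
                    template = matrix(1 / C, C, C),
                    schema = category_schema(c("neg", "pos")))
  expect_equal(expected_opa(cfg), C * (1 / C)^R, tolerance = 1e-12)
  m <- simulate_panel(cfg, seed = 8)
  e <- expected_opa(cfg)
  mc_se <- sqrt(e * (1 - e) / cfg$n_cases)
  expect_lt(abs(opa(m)$estimate - e), 3 * mc_se)
  # and the 4-category, 15-rater uniform panel has unanimity 4 * (1/4)^15
  cfg4 <- sim_config(n_cases = 10, n_raters = 15, prevalence = rep(0.25, 4),
                     template = matrix(0.25, 4, 4))
  expect_equal(expected_opa(cfg4), 4 * 0.25^15, tolerance = 1e-18)
})

test_that("recovery suite tracks the closed-form expectation over replicates", {
  cfg <- her2_default_config(n_cases = 250)
  rs <- recovery_suite(cfg, n_reps = 12, seed = 100)
  expect_equal(nrow(rs$reps), 12)
  expect_lt(abs(rs$mean["opa"] - rs$expected_opa), 3 * rs$mc_se_opa)
  # identity confusion: every replicate is exactly 1
  rsi <- recovery_suite(identity_config(30, 4), n_reps = 3, seed = 1)
  expect_true(all(rsi$reps$opa == 1))
  expect_true(all(rsi$reps$kappa == 1))
  expect_true(all(rsi$reps$icc == 1))
})

test_that("agreement decays monotonically in expectation as noise increases", {
  base <- her2_default_config(n_cases = 250)
  etas <- c(0, 0.25, 0.5, 0.75)
  means <- sapply(etas, function(e) {
    cfg <- sim_config(n_cases = 250, n_raters = 6, prevalence = base$prevalence,
                      template = base$template, smear = base$smear,
                      rater_noise = e)
    rs <- recovery_suite(cfg, n_reps = 6, seed = 200)
    rs$mean
  })
  expect_true(all(diff(means["opa", ]) < 0))
  expect_true(all(diff(means["kappa", ]) < 0))
  expect_true(all(diff(means["icc", ]) < 0))
  # the closed form is monotone too
  eo <- sapply(etas, function(e)
    expected_opa(sim_config(n_cases = 250, n_raters = 6,
                            prevalence = base$prevalence,
                            template = base$template, smear = base$smear,
                            rater_noise = e)))
  expect_true(all(diff(eo) < 0))
})

test_that("the shipped HER2-like configuration matches its calibration bands", {
  cfg <- her2_default_config()
  expect_equal(cfg$n_cases, 460L)
  expect_equal(cfg$n_raters, 15L)
  expect_equal(sum(cfg$strata == "senior"), 8)
  expect_equal(sum(cfg$strata == "junior"), 7)
  e <- expected_opa(cfg)
  expect_gt(e, 0.08); expect_lt(e, 0.22)
  m <- simulate_panel(cfg, seed = 1)
  o <- opa(m)$estimate
  expect_gt(o, 0.08); expect_lt(o, 0.22)
  # per-rater 3+ fractions within the tolerance band
  f3 <- rater_marginals(m)[["3+"]]
  expect_true(all(f3 > 0.05 & f3 < 0.25))
  # senior panels agree more often than junior panels (by construction)
  s <- stratified_opa(m, "observer_experience")
  expect_gt(s$opa[s$stratum == "senior"], s$opa[s$stratum == "junior"])
  # 0<->1+ confusion dominates the 0-subset discordance: within the cases
  # given a 0 by someone, non-0 ratings are mostly 1+, and more cases share
  # 0 with 1+ than 0 with 2+
  tab <- subset_rating_counts(m, "0")
  expect_gt(tab[["1+ counts"]], tab[["2+ counts"]])
  co <- subset_case_cooccurrence(m)
  expect_gt(co["0", "1+"], co["0", "2+"])
})

test_that("simulator configuration validation rejects invalid inputs", {
  expect_error(sim_config(10, 3, prevalence = c(0.5, 0.6, 0, 0),
                          template = diag(4)), "sum to 1")
  bad <- diag(4); bad[1, 1] <- 0.5
  expect_error(sim_config(10, 3, prevalence = rep(0.25, 4), template = bad),
               "rows must sum to 1")
  expect_error(sim_config(10, 3, prevalence = rep(0.25, 4), template = diag(4),
                          rater_noise = 2), "\\[0, 1\\]")
  expect_error(sim_config(10, 3, prevalence = rep(0.25, 4), template = diag(4),
                          strata = c("a", "b")), "one stratum per rater")
})
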