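test_that("OPA reproduces hand-computable ratios and intervals", {
  # 63 unanimous of 460 -> 0.137, displayed 0.14
  codes <- matrix(c(0L, 1L), 460, 2, byrow = TRUE)  # all discordant
  codes[1:63, 2] <- 0L                              # 63 unanimous
  e <- opa(score_matrix(codes))
  expect_equal(e$estimate, 63 / 460, tolerance = 1e-12)
  expect_identical(her2agree:::fmt2(e$estimate), "0.14")
  # Wilson interval displayed bounds match a large-panel report: (0.11-0.17)
  expect_identical(her2agree:::fmt2(e$lower), "0.11")
  expect_identical(her2agree:::fmt2(e$upper), "0.17")
  # identical observers
  m1 <- score_matrix(cbind(0:3, 0:3))
  expect_equal(opa(m1)$estimate, 1)
  expect_equal(opa(m1)$upper, 1)
})

test_that("Wilson interval has exact zero lower bound and brackets the estimate", {
  # 0 unanimous of 217: point 0.00, upper 0.0174 (displays 0.02)
  ci <- wilson_ci(0, 217)
  expect_identical(ci[1], 0)
  expect_equal(ci[2], 0.017394645, tolerance = 1e-6)
  expect_identical(her2agree:::fmt2(ci[2]), "0.02")
  set.seed(3)
  for (i in 1:20) {
    n <- sample(5:300, 1); x <- sample(0:n, 1)
    ci <- wilson_ci(x, n)
    expect_lte(ci[1], x / n + 1e-12)
    expect_gte(ci[2], x / n - 1e-12)
  }
  # Clopper-Pearson option agrees with the exact beta quantiles
  expect_equal(clopper_pearson_ci(0, 217)[2], 1 - 0.025^(1 / 217),
               tolerance = 1e-10)
})

test_that("Fleiss' kappa matches the naive-formula oracle on random tables", {
  set.seed(19)
  for (i in 1:10) {
    m <- random_panel(8, sample(3:6, 1))
    cnt <- count_table(m)
    expect_equal(fleiss_kappa(cnt)$estimate, brute_fleiss(cnt),
                 tolerance = 1e-12)
  }
})

test_that("Fleiss' kappa hits its boundary and degenerate cases", {
  # perfect agreement with >= 2 categories used
  m <- score_matrix(cbind(c(0L, 1L, 2L, 3L), c(0L, 1L, 2L, 3L), c(0L, 1L, 2L, 3L)))
  expect_equal(fleiss_kappa(m)$estimate, 1, tolerance = 1e-12)
  # all ratings in a single category: chance agreement 1, kappa undefined
  m2 <- score_matrix(matrix(1L, 4, 3))
  expect_true(is_undefined(fleiss_kappa(m2)))
  # interval is centred on the estimate
  m3 <- random_panel(12, 5)
  k <- fleiss_kappa(m3)
  expect_equal((k$lower + k$upper) / 2, k$estimate, tolerance = 1e-12)
  expect_error(fleiss_kappa(rbind(c(1, 2), c(2, 2))), "unbalanced")
})

test_that("ICC(A,1) matches the brute-force ANOVA oracle on random matrices", {
  set.seed(23)
  for (i in 1:10) {
    y <- matrix(sample(0:3, 40, replace = TRUE), 10, 4)
    if (stats::sd(y) == 0) next
    expect_equal(icc_a1(y)$estimate, brute_icc_a1(y), tolerance = 1e-12)
  }
})

test_that("ICC(A,1) agrees with an independent mixed-model implementation", {
  # frozen cross-check: two-way random-effects absolute-agreement single-rater
  # ICC of this 8x4 panel computed with an independent ANOVA implementation
  # gives 0.762712 with 95% CI (0.48, 0.94) to the printed precision
  y <- rbind(c(0, 1, 0, 1), c(2, 2, 3, 2), c(1, 1, 0, 2), c(3, 3, 3, 2),
             c(0, 0, 1, 0), c(2, 1, 2, 2), c(3, 3, 3, 3), c(1, 2, 2, 1))
  e <- icc_a1(y)
  expect_equal(e$estimate, 0.762712, tolerance = 1e-6)
  expect_equal(round(e$lower, 2), 0.48)
  expect_equal(round(e$upper, 2), 0.94)
})

test_that("ICC boundary behaviour: identical observers, zero variance", {
  # observers identical, cases varying -> perfect reliability
  y <- cbind(c(0, 1, 2, 3), c(0, 1, 2, 3), c(0, 1, 2, 3))
  expect_equal(icc_a1(y)$estimate, 1, tolerance = 1e-12)
  # no variance at all -> undefined signal, not 0 or 1
  expect_true(is_undefined(icc_a1(matrix(2, 5, 3))))
  expect_error(icc_a1(matrix(0:3, 1, 4)), "at least 2 cases")
})

test_that("agreement() fits all three metrics with accessors", {
  m <- random_panel(30, 5)
  fit <- agreement(m)
  expect_s3_class(fit, "agreement")
  co <- coef(fit)
  expect_named(co, c("opa", "fleiss_kappa", "icc"))
  ci <- confint(fit)
  expect_true(all(ci[, "lower"] <= co + 1e-12 & co <= ci[, "upper"] + 1e-12))
  expect_output(print(fit), "OPA")
  expect_output(summary(fit), "ANOVA mean squares")
})

test_that("table1_report assembles all groupings and degrades gracefully", {
  set.seed(29)
  m <- random_panel(60, 5)
  rep1 <- table1_report(m)
  expect_equal(nrow(rep1), 13)
  expect_identical(rep1$group[1:2],
                   c("4-category score (0, 1+, 2+, 3+)",
                     "3-category score (0, low, 3+)"))
  # dichotomized OPA never below the 4-category OPA
  expect_true(all(rep1$opa[8:13] >= rep1$opa[1]))
  # fully concordant panel: every defined row reports OPA 1
  mc <- score_matrix(cbind(c(0L, 3L), c(0L, 3L), c(0L, 3L)))
  repc <- table1_report(mc)
  expect_true(all(repc$opa[!is.na(repc$opa)] == 1))
  # empty subsets are reported as notes, not errors
  expect_true(any(is.na(repc$opa)) || all(repc$n_cases > 0))
  # wrong schema is refused
  expect_error(table1_report(recode(m, "three_cat")), "4-category")
})

test_that("stratified OPA separates noise strata and validates metadata", {
  cfg <- her2_default_config(n_cases = 200)
  m <- simulate_panel(cfg, seed = 31)
  s <- stratified_opa(m, "observer_experience")
  expect_equal(nrow(s), 2)
  senior <- s$opa[s$stratum == "senior"]
  junior <- s$opa[s$stratum == "junior"]
  expect_gt(senior, junior)  # lower-noise stratum agrees more often
  expect_equal(attr(s, "difference"), s$opa[1] - s$opa[2])
  sp <- stratified_opa(m, "specimen_type")
  expect_equal(sum(sp$n_cases), 200)
  # missing metadata errors name the sidecar
  m_bare <- score_matrix(m$scores)
  expect_error(stratified_opa(m_bare, "observer_experience"), "metadata")
  expect_error(stratified_opa(m_bare, "specimen_type"), "metadata")
  # a single-observer stratum cannot have an OPA
  m_one <- score_matrix(m$scores[, 1:3],
                        observer_meta = stats::setNames(
                          c("senior", "junior", "junior"),
                          colnames(m$scores[, 1:3])))
  expect_error(stratified_opa(m_one, "observer_experience"), "fewer than 2")
  # single stratum: one report row, difference undefined
  m_same <- score_matrix(m$scores[, 1:3],
                         observer_meta = stats::setNames(
                           rep("senior", 3), colnames(m$scores[, 1:3])))
  s1 <- stratified_opa(m_same, "observer_experience")
  expect_equal(nrow(s1), 1)
  expect_true(is.na(attr(s1, "difference")))
})
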