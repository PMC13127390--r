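test_that("CSV round trip preserves scores, identifiers and metadata", {
  m <- score_matrix(matrix(c(0L, 1L, 2L, 3L), 2, 2),
                    case_ids = c("a", "b"), observer_ids = c("p1", "p2"),
                    case_meta = c(a = "biopsy", b = "surgical"),
                    observer_meta = c(p1 = "senior", p2 = "junior"))
  d <- withr::local_tempdir()
  write_score_matrix(m, file.path(d, "s.csv"),
                     observer_meta_path = file.path(d, "o.csv"),
                     case_meta_path = file.path(d, "c.csv"))
  m2 <- read_score_matrix(file.path(d, "s.csv"),
                          observer_meta = file.path(d, "o.csv"),
                          case_meta = file.path(d, "c.csv"))
  expect_identical(m2$scores, m$scores)
  expect_identical(m2$case_ids, m$case_ids)
  expect_identical(m2$observer_ids, m$observer_ids)
  expect_identical(m2$case_meta, m$case_meta)
  expect_identical(m2$observer_meta, m$observer_meta)
})

test_that("label and numeric-code dialects are both accepted and normalised", {
  d <- withr::local_tempdir()
  f <- file.path(d, "labels.csv")
  writeLines(c("case_id,p1,p2", "c1,0,1+", "c2,2+,3+"), f)
  m <- read_score_matrix(f)
  expect_identical(unname(m$scores), matrix(c(0L, 2L, 1L, 3L), 2, 2))
  f2 <- file.path(d, "codes.csv")
  writeLines(c("case_id,p1,p2", "c1,0,1", "c2,2,3"), f2)
  expect_identical(read_score_matrix(f2)$scores, m$scores)
})

test_that("transposed (observer x case) layout is handled via the flag", {
  d <- withr::local_tempdir()
  f <- file.path(d, "t.csv")
  writeLines(c("observer_id,c1,c2,c3", "p1,0,1+,2+", "p2,3+,0,1+", "p3,1+,1+,1+"), f)
  m <- read_score_matrix(f, transposed = TRUE)
  expect_equal(dim(m$scores), c(3L, 3L))
  expect_identical(m$case_ids, c("c1", "c2", "c3"))
  expect_identical(m$observer_ids, c("p1", "p2", "p3"))
  expect_identical(unname(m$scores["c2", "p1"]), 1L)
})

test_that("invalid inputs are rejected with the offending entity named", {
  d <- withr::local_tempdir()
  f <- file.path(d, "bad.csv")
  writeLines(c("case_id,p1,p2", "c1,0,4+"), f)
  expect_error(read_score_matrix(f), "4\\+")
  expect_error(read_score_matrix(f), "c1")
  expect_error(read_score_matrix(f), "p2")
  writeLines(c("case_id,p1,p2", "c1,0,1+", "c1,2+,3+"), f)
  expect_error(read_score_matrix(f), "duplicate case")
  writeLines(c("case_id,p1,p1", "c1,0,1+"), f)
  expect_error(read_score_matrix(f), "duplicate observer")
  writeLines(c("case_id,p1,p2", "c1,0,", "c2,1+,2+"), f)
  expect_error(read_score_matrix(f), "empty cell|missing")
  writeLines(c("case_id,p1", "c1,0"), f)
  expect_error(read_score_matrix(f), "fewer than 2")
  expect_error(score_matrix(matrix(0L, 2, 1)), "at least 2 observers")
  expect_error(category_schema("only_one"), "at least 2 categories")
  expect_error(category_schema(c("a", "b"), c(1, 1)), "strictly increasing")
})

test_that("count table matches a per-cell tally loop and conserves observers", {
  m <- toy_matrix(rbind(c(0L, 0L, 1L), c(3L, 3L, 3L)))
  expect_identical(unname(count_table(m)),
                   rbind(c(2L, 1L, 0L, 0L), c(0L, 0L, 0L, 3L)))
  set.seed(42)
  for (i in 1:5) {
    m <- random_panel(6, 5)
    tab <- count_table(m)
    expect_identical(unname(tab), brute_count_table(m))
    expect_true(all(rowSums(tab) == ncol(m$scores)))
  }
})

test_that("rater marginals are row-normalised and match known fractions", {
  # an observer assigning 3+ to 34 of 460 cases has 3+ proportion 34/460
  codes <- matrix(0L, 460, 2)
  codes[1:34, 1] <- 3L
  codes[1:100, 2] <- 3L
  m <- score_matrix(codes)
  rm_ <- rater_marginals(m)
  expect_equal(rm_[["3+"]][1], 34 / 460, tolerance = 1e-12)
  expect_equal(round(rm_[["3+"]][1], 4), 0.0739)
  expect_true(all(abs(rowSums(rm_[, -1]) - 1) < 1e-12))
  # constant observer: all mass on one category
  m2 <- toy_matrix(cbind(rep(2L, 5), rep(2L, 5)))
  expect_equal(rater_marginals(m2)[["2+"]], c(1, 1))
})

test_that("case vote profile flags concordant cases and sums to 1", {
  m <- toy_matrix(rbind(c(2L, 2L, 2L), c(0L, 1L, 2L)))
  vp <- case_vote_profile(m)
  expect_equal(unlist(vp[1, c("0", "1+", "2+", "3+")], use.names = FALSE),
               c(0, 0, 1, 0))
  expect_identical(vp$concordant, c(TRUE, FALSE))
  expect_true(all(abs(rowSums(vp[, c("0", "1+", "2+", "3+")]) - 1) < 1e-12))
})

test_that("concordant-case count agrees with OPA across modules", {
  set.seed(7)
  for (i in 1:5) {
    m <- random_panel(30, 4, n_cat = 3)
    expect_equal(sum(case_vote_profile(m)$concordant),
                 opa(m)$estimate * nrow(m$scores), tolerance = 1e-12)
  }
})

test_that("the deposited-study loader refuses politely when the data are absent", {
  expect_error(her2_study_scores(path = NULL), "zenodo")
})
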