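# Independent brute-force oracles and fixture builders. Everything here is
# deliberately written as plain loops over the defining formulas, sharing no
# code with the package internals it checks.

toy_matrix <- function(codes, schema = her2_schema()) {
  score_matrix(matrix(codes, nrow = nrow(codes)), schema = schema)
}

random_panel <- function(n, r, n_cat = 4, schema = NULL) {
  if (is.null(schema))
    schema <- if (n_cat == 4) her2_schema()
    else category_schema(paste0("c", seq_len(n_cat)), seq_len(n_cat) - 1L)
  score_matrix(matrix(sample(schema$codes, n * r, replace = TRUE), n, r),
               schema = schema)
}

# cell-by-cell tally of observers per category
brute_count_table <- function(m) {
  C <- length(m$schema$labels)
  out <- matrix(0L, nrow(m$scores), C)
  for (i in seq_len(nrow(m$scores)))
    for (j in seq_len(ncol(m$scores)))
      for (cc in seq_len(C))
        if (m$scores[i, j] == m$schema$codes[cc])
          out[i, cc] <- out[i, cc] + 1L
  out
}

brute_opa <- function(m) {
  agree <- 0
  for (i in seq_len(nrow(m$scores)))
    if (length(unique(m$scores[i, ])) == 1) agree <- agree + 1
  agree / nrow(m$scores)
}

# direct double-loop evaluation of the Fleiss' kappa defining formula
brute_fleiss <- function(cnt) {
  n <- nrow(cnt); R <- sum(cnt[1, ]); C <- ncol(cnt)
  P <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(C)) s <- s + cnt[i, j]^2
    P[i] <- (s - R) / (R * (R - 1))
  }
  p <- numeric(C)
  for (j in seq_len(C)) p[j] <- sum(cnt[, j]) / (n * R)
  pe <- sum(p^2)
  (mean(P) - pe) / (1 - pe)
}

# explicit-summation two-way ANOVA and the ICC(A,1) defining formula
brute_icc_a1 <- function(y) {
  n <- nrow(y); k <- ncol(y)
  grand <- sum(y) / (n * k)
  rm_ <- rowSums(y) / k
  cm_ <- colSums(y) / n
  ssr <- 0; for (i in seq_len(n)) ssr <- ssr + (rm_[i] - grand)^2
  msr <- k * ssr / (n - 1)
  ssc <- 0; for (j in seq_len(k)) ssc <- ssc + (cm_[j] - grand)^2
  msc <- n * ssc / (k - 1)
  sse <- 0
  for (i in seq_len(n))
    for (j in seq_len(k))
      sse <- sse + (y[i, j] - rm_[i] - cm_[j] + grand)^2
  mse <- sse / ((n - 1) * (k - 1))
  unname((msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse)))
}

# all orderings of 1..r by recursion (independent of the package's enumerator)
brute_perms <- function(r) {
  if (r == 1) return(matrix(1, 1, 1))
  smaller <- brute_perms(r - 1)
  out <- NULL
  for (lead in seq_len(r)) {
    rest <- setdiff(seq_len(r), lead)
    out <- rbind(out, cbind(lead, matrix(rest[smaller], nrow(smaller))))
  }
  unname(out)
}

# OPA of the first k observers of ordering p, straight from the definition
brute_onest_band <- function(m, stat = min) {
  r <- ncol(m$scores)
  perms <- brute_perms(r)
  vals <- matrix(NA_real_, nrow(perms), r - 1)
  for (pi in seq_len(nrow(perms)))
    for (k in 2:r) {
      sub <- m$scores[, perms[pi, 1:k], drop = FALSE]
      agree <- 0
      for (i in seq_len(nrow(sub)))
        if (length(unique(sub[i, ])) == 1) agree <- agree + 1
      vals[pi, k - 1] <- agree / nrow(sub)
    }
  apply(vals, 2, stat)
}
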