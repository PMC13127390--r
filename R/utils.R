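# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Commercial ("half-up") rounding used for report display, so that e.g.
#' 0.135 renders as 0.14. R's [round()] rounds half to even, which does not
#' match how clinical tables are usually typeset.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Format an estimate for 2-decimal table display.
fmt2 <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.2f", round_half_up(x, 2)))
}

# Deterministic per-analysis seed substream: a single top-level seed is fanned
# out so e.g. the ONEST permutations and the simulator draw independent streams.
seed_stream <- function(seed, stream) {
  offs <- c(simulate = 1000003L, onest = 2000003L, recovery = 3000017L,
            analysis = 4000037L)
  if (!stream %in% names(offs)) stop("unknown seed stream: ", stream)
  as.integer((as.double(seed) + offs[[stream]]) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards (the polite simulate()-style contract).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# A typed "undefined statistic" marker so degenerate inputs (single-category
# matrices, zero variance) degrade gracefully in reports instead of returning
# a misleading 0 or 1.
undefined_stat <- function(reason) {
  structure(list(estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                 reason = reason),
            class = c("undefined_stat", "agree_est"))
}

#' Test whether a statistic is the typed "undefined" marker
#'
#' @param x object returned by one of the agreement estimators.
#' @return `TRUE` if `x` carries an undefined-statistic signal.
#' @export
is_undefined <- function(x) inherits(x, "undefined_stat")

agree_est <- function(estimate, lower, upper, method, n = NA_integer_) {
  structure(list(estimate = estimate, lower = lower, upper = upper,
                 method = method, n = n),
            class = "agree_est")
}

#' @export
print.agree_est <- function(x, ...) {
  if (is_undefined(x)) {
    cat("undefined (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf("%.4f (95%% CI %.4f-%.4f)%s\n", x$estimate, x$lower, x$upper,
                if (!is.null(x$method)) paste0(" [", x$method, "]") else ""))
  }
  invisible(x)
}
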