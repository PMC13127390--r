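#' ONEST: agreement as a function of panel size
#'
#' The Observers Needed to Evaluate a Subjective Test procedure traces how
#' overall percent agreement decays as hypothetical panels grow. For each
#' random ordering of the R observers and each k = 2..R, the OPA of the first
#' k observers in that ordering is recorded; the per-k minimum, mean and
#' maximum across orderings summarise the curve family, and the panel size at
#' which the mean curve stops moving is the plateau estimate.
#'
#' Orderings are sampled independently and uniformly (with replacement in
#' permutation space); `exhaustive = TRUE` enumerates all R! orderings
#' instead, permitted while R! does not exceed `max_exhaustive`.
#'
#' @param m a [score_matrix()] with at least 3 observers.
#' @param n_permutations number of observer orderings to sample (default 1000).
#' @param seed integer seed; required for a reproducible curve set.
#' @param exhaustive enumerate all R! orderings instead of sampling.
#' @param max_exhaustive largest R! allowed in exhaustive mode.
#' @param plateau_epsilon OPA tolerance defining the plateau (default 0.01).
#' @return an object of class `onest`: `sizes` (2..R), `curves` (one row per
#'   ordering), `band` (per-k min/mean/max), `plateau_k`, `opa_full`.
#' @examples
#' cfg <- her2_default_config(n_cases = 80)
#' os <- onest(simulate_panel(cfg, seed = 2), n_permutations = 50, seed = 3)
#' os$plateau_k
#' @export
onest <- function(m, n_permutations = 1000, seed = NULL, exhaustive = FALSE,
                  max_exhaustive = 5040, plateau_epsilon = 0.01) {
  stopifnot(inherits(m, "score_matrix"))
  R <- ncol(m$scores)
  if (R < 3) stop("ONEST needs at least 3 observers (a 2-observer panel is a single point)")
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  if (plateau_epsilon <= 0) stop("plateau_epsilon must be > 0")
  if (exhaustive) {
    if (factorial(R) > max_exhaustive)
      stop("exhaustive mode refused: ", R, "! = ", factorial(R),
           " orderings exceeds max_exhaustive = ", max_exhaustive)
    perms <- all_permutations(R)
  } else {
    perms <- with_seed(seed,
      t(replicate(n_permutations, sample.int(R))))
  }
  curves <- t(apply(perms, 1, function(p) opa_curve(m$scores[, p, drop = FALSE])))
  sizes <- 2:R
  colnames(curves) <- paste0("k", sizes)
  band <- data.frame(k = sizes,
                     min = apply(curves, 2, min),
                     mean = colMeans(curves),
                     max = apply(curves, 2, max))
  rownames(band) <- NULL
  out <- structure(list(sizes = sizes, curves = curves, band = band,
                        n_permutations = nrow(perms),
                        exhaustive = exhaustive, seed = seed,
                        plateau_epsilon = plateau_epsilon,
                        opa_full = unname(band$mean[length(sizes)])),
                   class = "onest")
  out$plateau_k <- plateau(out, plateau_epsilon)
  out
}

# OPA of the first k columns, for k = 2..R, via cumulative agreement with the
# first observer in the ordering: case i is unanimous among the first k
# observers iff observers 2..k all match observer 1.
opa_curve <- function(s) {
  eq <- s == s[, 1]
  for (j in 2:ncol(s)) eq[, j] <- eq[, j - 1] & eq[, j]
  colMeans(eq)[-1]
}

all_permutations <- function(R) {
  perm_list <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perm_list(v[-i]), function(p) c(v[i], p)))
    out
  }
  do.call(rbind, perm_list(seq_len(R)))
}

#' Plateau of an ONEST curve set
#'
#' The smallest panel size k such that the mean OPA curve stays within
#' `epsilon` of its value at the full panel for every k' >= k; returns R when
#' no earlier size qualifies. A curve set from identical observers plateaus
#' at k = 2.
#'
#' @param cs an `onest` object.
#' @param epsilon OPA tolerance (defaults to the value stored in `cs`).
#' @return integer panel size.
#' @export
plateau <- function(cs, epsilon = cs$plateau_epsilon) {
  stopifnot(inherits(cs, "onest"))
  mean_curve <- cs$band$mean
  target <- mean_curve[length(mean_curve)]
  ok <- abs(mean_curve - target) <= epsilon
  # smallest k from which every later point also qualifies
  ok_tail <- rev(cumprod(rev(ok))) > 0
  cs$sizes[which(ok_tail)[1]]
}

#' @export
print.onest <- function(x, ...) {
  cat(sprintf("ONEST curve set: %d orderings%s over %d observer sizes (k = %d..%d)\n",
              x$n_permutations, if (x$exhaustive) " (exhaustive)" else "",
              length(x$sizes), min(x$sizes), max(x$sizes)))
  cat(sprintf("  full-panel OPA %.4f; mean-curve plateau at k = %d (epsilon = %g)\n",
              x$opa_full, x$plateau_k, x$plateau_epsilon))
  invisible(x)
}

#' @export
summary.onest <- function(object, ...) {
  print(object)
  print(round(object$band, 4), row.names = FALSE)
  invisible(object)
}

#' Plot an ONEST curve set
#'
#' Spaghetti plot of the per-ordering OPA curves with the min/max envelope
#' and the mean curve, plus the plateau size.
#'
#' @param x an `onest` object.
#' @param max_curves number of individual curves to overplot.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.onest <- function(x, max_curves = 100, ...) {
  idx <- seq_len(min(max_curves, nrow(x$curves)))
  graphics::matplot(x$sizes, t(x$curves[idx, , drop = FALSE]), type = "l",
                    lty = 1, col = grDevices::grey(0.8), xlab = "observers",
                    ylab = "overall percent agreement", ylim = c(0, 1), ...)
  graphics::lines(x$sizes, x$band$min, lty = 2)
  graphics::lines(x$sizes, x$band$max, lty = 2)
  graphics::lines(x$sizes, x$band$mean, lwd = 2)
  graphics::abline(v = x$plateau_k, lty = 3)
  invisible(x)
}

#' Export ONEST curves in long format
#'
#' @param cs an `onest` object.
#' @return data frame with columns `permutation`, `k`, `opa` (one row per
#'   ordering and panel size), suitable for replotting.
#' @export
onest_long <- function(cs) {
  stopifnot(inherits(cs, "onest"))
  data.frame(permutation = rep(seq_len(nrow(cs$curves)), times = length(cs$sizes)),
             k = rep(cs$sizes, each = nrow(cs$curves)),
             opa = as.vector(cs$curves))
}
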