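#' Full agreement report across scoring schemes, subsets and dichotomizations
#'
#' Assembles the standard concordance table for a 4-category HER2 panel: the
#' full 4-category scheme; the merged 3-category scheme (0 / low / 3+); the
#' five "score assigned by at least one observer" subsets (0, 1+, 2+, 3+,
#' low — the union of 1+ and 2+), whose statistics are computed on the
#' original 4-category codes; and the six built-in dichotomizations. Each row
#' carries OPA, Fleiss' kappa and ICC(A,1) with 95% intervals. Rows whose
#' statistic is undefined (for instance an empty subset) are reported with a
#' note instead of aborting the table.
#'
#' @param m a [score_matrix()] on the 4-category HER2 schema.
#' @param ci_method OPA interval method, see [opa()].
#' @return a data frame of class `table1_report`, one row per grouping.
#' @export
table1_report <- function(m, ci_method = c("wilson", "clopper-pearson")) {
  stopifnot(inherits(m, "score_matrix"))
  ci_method <- match.arg(ci_method)
  if (!identical(m$schema$labels, her2_schema()$labels))
    stop("table1_report expects the 4-category HER2 schema")
  specs <- list(
    list(name = "4-category score (0, 1+, 2+, 3+)",
         build = function(m) m),
    list(name = "3-category score (0, low, 3+)",
         build = function(m) recode(m, "three_cat")),
    list(name = "0 only", build = function(m) select_subset(m, "0")),
    list(name = "1+ only", build = function(m) select_subset(m, "1+")),
    list(name = "2+ only", build = function(m) select_subset(m, "2+")),
    list(name = "3+ only", build = function(m) select_subset(m, "3+")),
    list(name = "low only",
         build = function(m) select_subset(m, c("1+", "2+"))),
    list(name = "0 vs. not 0", build = function(m) recode(m, "0_vs_not0")),
    list(name = "1+ vs. not 1+", build = function(m) recode(m, "1_vs_not1")),
    list(name = "2+ vs. not 2+", build = function(m) recode(m, "2_vs_not2")),
    list(name = "low vs. not low",
         build = function(m) recode(m, "low_vs_notlow")),
    list(name = "3+ vs. not 3+", build = function(m) recode(m, "3_vs_not3")),
    list(name = "<2+ vs. >=2+", build = function(m) recode(m, "lt2_vs_ge2"))
  )
  rows <- lapply(specs, function(sp) {
    fit <- tryCatch(agreement(sp$build(m), ci_method = ci_method,
                              grouping_name = sp$name),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      return(data.frame(group = sp$name, n_cases = 0L,
                        opa = NA_real_, opa_lower = NA_real_, opa_upper = NA_real_,
                        kappa = NA_real_, kappa_lower = NA_real_, kappa_upper = NA_real_,
                        icc = NA_real_, icc_lower = NA_real_, icc_upper = NA_real_,
                        note = conditionMessage(fit), stringsAsFactors = FALSE))
    }
    note <- character(0)
    if (is_undefined(fit$kappa)) note <- c(note, paste0("kappa ", fit$kappa$reason))
    if (is_undefined(fit$icc)) note <- c(note, paste0("ICC ", fit$icc$reason))
    data.frame(group = sp$name, n_cases = fit$n_cases,
               opa = fit$opa$estimate, opa_lower = fit$opa$lower,
               opa_upper = fit$opa$upper,
               kappa = fit$kappa$estimate, kappa_lower = fit$kappa$lower,
               kappa_upper = fit$kappa$upper,
               icc = fit$icc$estimate, icc_lower = fit$icc$lower,
               icc_upper = fit$icc$upper,
               note = if (length(note)) paste(note, collapse = "; ") else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("table1_report", "data.frame")
  out
}

#' @export
print.table1_report <- function(x, ...) {
  trip <- function(e, l, u)
    ifelse(is.na(e), "--", sprintf("%s (%s-%s)", fmt2(e), fmt2(l), fmt2(u)))
  disp <- data.frame(
    group = x$group, n = x$n_cases,
    OPA = trip(x$opa, x$opa_lower, x$opa_upper),
    `Fleiss kappa` = trip(x$kappa, x$kappa_lower, x$kappa_upper),
    ICC = trip(x$icc, x$icc_lower, x$icc_upper),
    check.names = FALSE)
  print(disp, row.names = FALSE, right = FALSE)
  notes <- x$note[nzchar(x$note)]
  if (length(notes)) cat("notes:", paste(unique(notes), collapse = "; "), "\n")
  invisible(x)
}

#' Stratified overall percent agreement
#'
#' Splits the panel along one metadata axis and reports OPA per stratum plus
#' the between-stratum difference. For the observer axis (experience), OPA is
#' computed among each stratum's observers over all cases; for the case axis
#' (specimen type), over each stratum's cases among all observers.
#'
#' @param m a [score_matrix()] carrying the relevant metadata.
#' @param axis `"observer_experience"` or `"specimen_type"`.
#' @param ci_method OPA interval method.
#' @return data frame with one row per stratum (`stratum`, `n_cases`,
#'   `n_observers`, `opa`, `lower`, `upper`); the attribute `"difference"`
#'   holds first-minus-second stratum OPA when exactly two strata exist,
#'   otherwise `NA`.
#' @export
stratified_opa <- function(m, axis = c("observer_experience", "specimen_type"),
                           ci_method = c("wilson", "clopper-pearson")) {
  stopifnot(inherits(m, "score_matrix"))
  axis <- match.arg(axis)
  ci_method <- match.arg(ci_method)
  if (axis == "observer_experience") {
    if (is.null(m$observer_meta))
      stop("observer metadata (experience sidecar) is missing")
    strata <- unique(m$observer_meta)
    rows <- lapply(strata, function(s) {
      obs <- m$observer_ids[m$observer_meta == s]
      if (length(obs) < 2)
        stop("stratum '", s, "' has fewer than 2 observers")
      sub <- score_matrix(m$scores[, obs, drop = FALSE],
                          case_ids = m$case_ids, observer_ids = obs,
                          schema = m$schema)
      e <- opa(sub, ci = ci_method)
      data.frame(stratum = s, n_cases = nrow(m$scores),
                 n_observers = length(obs), opa = e$estimate,
                 lower = e$lower, upper = e$upper, stringsAsFactors = FALSE)
    })
  } else {
    if (is.null(m$case_meta))
      stop("case metadata (specimen type sidecar) is missing")
    strata <- unique(m$case_meta)
    rows <- lapply(strata, function(s) {
      keep <- m$case_meta == s
      sub <- score_matrix(m$scores[keep, , drop = FALSE],
                          case_ids = m$case_ids[keep],
                          observer_ids = m$observer_ids, schema = m$schema)
      e <- opa(sub, ci = ci_method)
      data.frame(stratum = s, n_cases = sum(keep),
                 n_observers = ncol(m$scores), opa = e$estimate,
                 lower = e$lower, upper = e$upper, stringsAsFactors = FALSE)
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "difference") <-
    if (nrow(out) == 2) out$opa[1] - out$opa[2] else NA_real_
  attr(out, "axis") <- axis
  out
}
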