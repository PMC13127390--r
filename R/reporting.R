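#' Configuration for a full panel analysis run
#'
#' Bundles input paths, the requested analyses and the run seed for
#' [run_full_analysis()]. A seed is mandatory whenever a stochastic analysis
#' (`"onest"` or `"simulate"`) is requested; it is fanned out into named
#' substreams so each analysis is independently reproducible.
#'
#' @param scores path to the score-matrix CSV (omit when only `"simulate"`
#'   is requested).
#' @param analyses character subset of `"table1"`, `"crosstabs"`,
#'   `"profiles"`, `"onest"`, `"stratified"`, `"simulate"`.
#' @param out_dir output directory (created if absent).
#' @param observer_meta,case_meta optional metadata sidecar paths.
#' @param seed integer run seed.
#' @param transposed score CSV is observer-by-case.
#' @param onest_permutations,onest_epsilon ONEST overrides.
#' @param onest_group built-in recode-map name, `"<anchor> only"` subset name
#'   or `"4cat"` — the grouping the ONEST analysis runs on.
#' @param sim_config a [sim_config()] for `"simulate"` runs (default the
#'   shipped HER2-like configuration).
#' @return an object of class `run_config`.
#' @export
run_config <- function(scores = NULL, analyses = "table1", out_dir = ".",
                       observer_meta = NULL, case_meta = NULL, seed = NULL,
                       transposed = FALSE, onest_permutations = 1000,
                       onest_epsilon = 0.01, onest_group = "4cat",
                       sim_config = her2_default_config()) {
  analyses <- match.arg(analyses,
                        c("table1", "crosstabs", "profiles", "onest",
                          "stratified", "simulate"), several.ok = TRUE)
  if (!length(analyses)) stop("requested analyses must be non-empty")
  needs_seed <- any(c("onest", "simulate") %in% analyses)
  if (needs_seed && is.null(seed))
    stop("a seed is required when a stochastic analysis (onest/simulate) is requested")
  needs_scores <- length(setdiff(analyses, "simulate")) > 0
  if (needs_scores && is.null(scores))
    stop("a score CSV is required for the requested analyses")
  structure(list(scores = scores, analyses = analyses, out_dir = out_dir,
                 observer_meta = observer_meta, case_meta = case_meta,
                 seed = seed, transposed = transposed,
                 onest_permutations = onest_permutations,
                 onest_epsilon = onest_epsilon, onest_group = onest_group,
                 sim_config = sim_config),
            class = "run_config")
}

#' Run the full panel analysis described by a configuration
#'
#' Executes each requested analysis, writes every table as a TSV/JSON twin
#' under `cfg$out_dir`, and finishes with a `manifest.json` listing every
#' file written, its MD5 checksum and the parameters that produced it. The
#' run is deterministic given the inputs and seed: re-running the same
#' configuration reproduces byte-identical outputs. Row-level problems
#' (undefined statistics, empty subsets) are collected as warnings in the
#' manifest rather than aborting the run.
#'
#' @param cfg a [run_config()].
#' @param quiet suppress progress messages (they go to standard error).
#' @return the manifest, invisibly.
#' @export
run_full_analysis <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  files <- list()
  warnings <- character(0)
  params <- list(seed = cfg$seed, analyses = cfg$analyses)
  emit <- function(df, stem) {
    tsv <- file.path(cfg$out_dir, paste0(stem, ".tsv"))
    utils::write.table(df, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
    js <- file.path(cfg$out_dir, paste0(stem, ".json"))
    jsonlite::write_json(df, js, dataframe = "rows", digits = NA, pretty = TRUE)
    files[c(tsv, js)] <<- c(tsv, js)
  }

  m <- NULL
  if (!is.null(cfg$scores)) {
    if (!file.exists(cfg$scores))
      stop("cannot read score matrix: '", cfg$scores, "' not found")
    m <- read_score_matrix(cfg$scores, transposed = cfg$transposed,
                           observer_meta = cfg$observer_meta,
                           case_meta = cfg$case_meta)
    say(sprintf("loaded %d cases x %d observers from %s",
                nrow(m$scores), ncol(m$scores), cfg$scores))
  }

  if ("table1" %in% cfg$analyses) {
    say("computing agreement report (table1)")
    rep1 <- table1_report(m)
    warnings <- c(warnings, rep1$note[nzchar(rep1$note)])
    emit(as.data.frame(rep1), "table1")
  }
  if ("crosstabs" %in% cfg$analyses) {
    say("computing subset cross-tabulations")
    emit(subset_rating_counts(m), "subset_rating_counts")
    co <- subset_case_cooccurrence(m)
    emit(data.frame(subset = paste0(rownames(co), " only"), co,
                    total_cases = diag(co), check.names = FALSE),
         "subset_case_cooccurrence")
  }
  if ("profiles" %in% cfg$analyses) {
    say("exporting per-observer and per-case score profiles")
    emit(rater_marginals(m), "rater_marginals")
    emit(case_vote_profile(m), "case_vote_profile")
  }
  if ("onest" %in% cfg$analyses) {
    g <- cfg$onest_group
    say("running ONEST on grouping '", g, "'")
    mg <- if (identical(g, "4cat")) m
    else if (grepl(" only$", g)) select_subset(m, sub(" only$", "", g))
    else recode(m, g)
    os <- onest(mg, n_permutations = cfg$onest_permutations,
                seed = seed_stream(cfg$seed, "onest"),
                plateau_epsilon = cfg$onest_epsilon)
    emit(onest_long(os), "onest_curves")
    emit(os$band, "onest_band")
    params$onest <- list(group = g, n_permutations = os$n_permutations,
                         epsilon = os$plateau_epsilon,
                         plateau_k = os$plateau_k, opa_full = os$opa_full)
  }
  if ("stratified" %in% cfg$analyses) {
    say("computing stratified OPA")
    if (is.null(m$observer_meta) && is.null(cfg$observer_meta))
      stop("stratified analysis requested but the observer experience ",
           "sidecar (observer_meta) is missing")
    s <- stratified_opa(m, "observer_experience")
    s$axis <- "observer_experience"
    s$difference <- attr(s, "difference")
    if (!is.null(m$case_meta)) {
      s2 <- stratified_opa(m, "specimen_type")
      s2$axis <- "specimen_type"
      s2$difference <- attr(s2, "difference")
      s <- rbind(s, s2)
    }
    emit(s, "stratified_opa")
  }
  if ("simulate" %in% cfg$analyses) {
    say("simulating a synthetic panel")
    sim <- simulate_panel(cfg$sim_config,
                          seed = seed_stream(cfg$seed, "simulate"))
    sp <- file.path(cfg$out_dir, "simulated_scores.csv")
    write_score_matrix(sim, sp,
                       observer_meta_path = file.path(cfg$out_dir,
                                                      "simulated_observers.csv"),
                       case_meta_path = file.path(cfg$out_dir,
                                                  "simulated_cases.csv"))
    written <- c(sp, file.path(cfg$out_dir, "simulated_observers.csv"),
                 file.path(cfg$out_dir, "simulated_cases.csv"))
    written <- written[file.exists(written)]
    files[written] <- written
    params$simulate <- list(n_cases = cfg$sim_config$n_cases,
                            n_raters = cfg$sim_config$n_raters,
                            expected_opa = expected_opa(cfg$sim_config))
  }

  manifest <- list(
    package = "her2agree",
    version = as.character(utils::packageVersion("her2agree")),
    params = params,
    warnings = unique(warnings),
    files = lapply(unname(files), function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f))))
  )
  mpath <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  say("wrote ", length(files), " files + manifest to ", cfg$out_dir)
  invisible(manifest)
}
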