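#' Case-by-observer score matrix
#'
#' The central data container: an N-case by R-observer grid of ordinal
#' category codes drawn from a [category_schema()], with optional per-case
#' specimen metadata and per-observer experience metadata. Every observer must
#' have scored every case (balanced complete panels; missing cells are
#' rejected, not imputed, because all the agreement formulas here assume a
#' constant number of ratings per case).
#'
#' @param scores integer matrix (cases in rows, observers in columns) of
#'   schema codes, or a character matrix of schema labels.
#' @param case_ids,observer_ids unique identifiers; defaults are taken from
#'   `dimnames(scores)` or generated.
#' @param schema a [category_schema()].
#' @param case_meta optional named character vector mapping case id to
#'   specimen type (e.g. `"biopsy"` / `"surgical"`).
#' @param observer_meta optional named character vector mapping observer id to
#'   experience stratum (e.g. `"senior"` / `"junior"`).
#' @return an object of class `score_matrix`.
#' @examples
#' m <- score_matrix(matrix(c(0, 0, 1, 3, 3, 3), nrow = 2, byrow = TRUE),
#'                   schema = her2_schema())
#' opa(m)
#' @export
score_matrix <- function(scores, case_ids = NULL, observer_ids = NULL,
                         schema = her2_schema(), case_meta = NULL,
                         observer_meta = NULL) {
  if (is.character(scores)) {
    codes <- schema_match(scores, schema)
    bad <- which(is.na(codes) & !is.na(scores))
    if (length(bad)) stop("unknown category token: '", scores[bad[1]], "'")
    scores <- matrix(codes, nrow = nrow(scores), dimnames = dimnames(scores))
  }
  scores <- as.matrix(scores)
  storage.mode(scores) <- "integer"
  case_ids <- as.character(case_ids %||% rownames(scores) %||%
                             paste0("case_", seq_len(nrow(scores))))
  observer_ids <- as.character(observer_ids %||% colnames(scores) %||%
                                 paste0("obs_", seq_len(ncol(scores))))
  validate_score_matrix(scores, case_ids, observer_ids, schema)
  dimnames(scores) <- list(case_ids, observer_ids)
  m <- structure(list(scores = scores, schema = schema,
                      case_ids = case_ids, observer_ids = observer_ids,
                      case_meta = NULL, observer_meta = NULL),
                 class = "score_matrix")
  if (!is.null(case_meta)) m <- set_case_meta(m, case_meta)
  if (!is.null(observer_meta)) m <- set_observer_meta(m, observer_meta)
  m
}

validate_score_matrix <- function(scores, case_ids, observer_ids, schema) {
  n <- nrow(scores); r <- ncol(scores)
  if (n < 1) stop("score matrix needs at least 1 case")
  if (r < 2) stop("score matrix needs at least 2 observers")
  if (length(case_ids) != n) stop("case_ids length must equal row count")
  if (length(observer_ids) != r) stop("observer_ids length must equal column count")
  if (anyDuplicated(case_ids))
    stop("duplicate case identifier: '", case_ids[duplicated(case_ids)][1], "'")
  if (anyDuplicated(observer_ids))
    stop("duplicate observer identifier: '",
         observer_ids[duplicated(observer_ids)][1], "'")
  if (anyNA(scores)) {
    ij <- which(is.na(scores), arr.ind = TRUE)[1, ]
    stop("missing score for case '", case_ids[ij[1]], "', observer '",
         observer_ids[ij[2]], "' (missing data are rejected, not imputed)")
  }
  bad <- !(scores %in% schema$codes)
  if (any(bad)) {
    ij <- which(matrix(bad, nrow = n), arr.ind = TRUE)[1, ]
    stop("invalid category code ", scores[ij[1], ij[2]], " for case '",
         case_ids[ij[1]], "', observer '", observer_ids[ij[2]], "'")
  }
  invisible(TRUE)
}

set_case_meta <- function(m, meta) {
  meta <- stats::setNames(as.character(meta), names(meta))
  miss <- setdiff(m$case_ids, names(meta))
  if (length(miss))
    stop("case metadata missing for case '", miss[1], "'")
  m$case_meta <- meta[m$case_ids]
  m
}

set_observer_meta <- function(m, meta) {
  meta <- stats::setNames(as.character(meta), names(meta))
  miss <- setdiff(m$observer_ids, names(meta))
  if (length(miss))
    stop("observer metadata missing for observer '", miss[1], "'")
  m$observer_meta <- meta[m$observer_ids]
  m
}

#' @export
dim.score_matrix <- function(x) dim(x$scores)

#' @export
as.matrix.score_matrix <- function(x, labels = FALSE, ...) {
  if (!labels) return(x$scores)
  matrix(schema_label(x$scores, x$schema), nrow = nrow(x$scores),
         dimnames = dimnames(x$scores))
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("score matrix: %d cases x %d observers, categories %s\n",
              nrow(x$scores), ncol(x$scores),
              paste(x$schema$labels, collapse = "/")))
  if (!is.null(x$observer_meta))
    cat("  observer strata:",
        paste(sprintf("%s=%d", names(table(x$observer_meta)),
                      table(x$observer_meta)), collapse = ", "), "\n")
  if (!is.null(x$case_meta))
    cat("  case strata:",
        paste(sprintf("%s=%d", names(table(x$case_meta)),
                      table(x$case_meta)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.score_matrix <- function(object, ...) {
  print(object)
  cat("overall category use:\n")
  tab <- table(factor(schema_label(object$scores, object$schema),
                      levels = object$schema$labels))
  print(round(prop.table(tab), 4))
  invisible(object)
}

#' Read a score matrix from CSV
#'
#' Expects a header row of observer identifiers with a leading case-identifier
#' column; cells may be schema labels (`"1+"`) or their numeric codes (`1`) in
#' any mixture — both dialects are normalised to codes. `transposed = TRUE`
#' accepts the observer-by-case layout instead.
#'
#' @param path CSV file path.
#' @param schema a [category_schema()].
#' @param transposed if `TRUE` rows are observers and columns are cases.
#' @param observer_meta,case_meta optional paths to metadata sidecar CSVs
#'   (`observer_id,experience` and `case_id,specimen_type`).
#' @return a validated [score_matrix()].
#' @export
read_score_matrix <- function(path, schema = her2_schema(), transposed = FALSE,
                              observer_meta = NULL, case_meta = NULL) {
  if (!file.exists(path)) stop("cannot read score matrix: '", path, "' not found")
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        na.strings = NULL)
  if (ncol(df) < 2) stop("score CSV needs an identifier column plus scores")
  ids <- df[[1]]
  cells <- as.matrix(df[, -1, drop = FALSE])
  if (transposed) {
    cells <- t(cells)
    case_ids <- colnames(df)[-1]
    observer_ids <- ids
  } else {
    case_ids <- ids
    observer_ids <- colnames(df)[-1]
  }
  if (length(observer_ids) < 2)
    stop("fewer than 2 observer columns in '", path, "'")
  if (anyDuplicated(case_ids))
    stop("duplicate case identifier: '", case_ids[duplicated(case_ids)][1], "'")
  if (anyDuplicated(observer_ids))
    stop("duplicate observer identifier: '",
         observer_ids[duplicated(observer_ids)][1], "'")
  empty <- which(trimws(cells) == "", arr.ind = TRUE)
  if (nrow(empty)) {
    stop("empty cell for case '", case_ids[empty[1, 1]], "', observer '",
         observer_ids[empty[1, 2]], "' (missing data are rejected)")
  }
  codes <- schema_match(cells, schema)
  if (anyNA(codes)) {
    ij <- which(matrix(is.na(codes), nrow = nrow(cells)), arr.ind = TRUE)[1, ]
    stop("unknown category token '", cells[ij[1], ij[2]], "' for case '",
         case_ids[ij[1]], "', observer '", observer_ids[ij[2]], "'")
  }
  m <- score_matrix(matrix(codes, nrow = length(case_ids)),
                    case_ids = case_ids, observer_ids = observer_ids,
                    schema = schema)
  if (!is.null(observer_meta)) m <- set_observer_meta(m, read_meta(observer_meta))
  if (!is.null(case_meta)) m <- set_case_meta(m, read_meta(case_meta))
  m
}

read_meta <- function(path) {
  if (!file.exists(path)) stop("metadata sidecar '", path, "' not found")
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("metadata sidecar needs 2 columns (id, value)")
  stats::setNames(df[[2]], df[[1]])
}

#' Write a score matrix (and metadata sidecars) to CSV
#'
#' Cells are always written as category labels, whatever dialect was read.
#'
#' @param m a [score_matrix()].
#' @param path output CSV path.
#' @param observer_meta_path,case_meta_path optional sidecar output paths.
#' @return `path`, invisibly.
#' @export
write_score_matrix <- function(m, path, observer_meta_path = NULL,
                               case_meta_path = NULL) {
  lab <- as.matrix(m, labels = TRUE)
  df <- data.frame(case_id = m$case_ids, lab, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("case_id", m$observer_ids)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(observer_meta_path) && !is.null(m$observer_meta))
    utils::write.csv(data.frame(observer_id = names(m$observer_meta),
                                experience = unname(m$observer_meta)),
                     observer_meta_path, row.names = FALSE, quote = FALSE)
  if (!is.null(case_meta_path) && !is.null(m$case_meta))
    utils::write.csv(data.frame(case_id = names(m$case_meta),
                                specimen_type = unname(m$case_meta)),
                     case_meta_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-case category count table
#'
#' The N x C table whose entry (i, j) counts the observers assigning case i
#' category j — the sufficient statistic for overall percent agreement and
#' Fleiss' kappa. Rows always sum to the number of observers.
#'
#' @param m a [score_matrix()].
#' @return integer matrix with one row per case, one column per category.
#' @export
count_table <- function(m) {
  stopifnot(inherits(m, "score_matrix"))
  C <- n_categories(m$schema)
  idx <- match(m$scores, m$schema$codes)
  dim(idx) <- dim(m$scores)
  out <- t(apply(idx, 1, tabulate, nbins = C))
  dimnames(out) <- list(m$case_ids, m$schema$labels)
  storage.mode(out) <- "integer"
  out
}

#' Per-observer category proportions
#'
#' The marginal score distribution of each observer (the stacked-bar-per-
#' pathologist view of a panel), in the observer order of the matrix.
#'
#' @param m a [score_matrix()].
#' @return data frame with `observer_id` and one proportion column per
#'   category; proportion rows sum to 1.
#' @export
rater_marginals <- function(m) {
  stopifnot(inherits(m, "score_matrix"))
  C <- n_categories(m$schema)
  idx <- match(m$scores, m$schema$codes)
  dim(idx) <- dim(m$scores)
  props <- t(apply(idx, 2, function(col) tabulate(col, nbins = C) / length(col)))
  out <- data.frame(observer_id = m$observer_ids, props,
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out) <- c("observer_id", m$schema$labels)
  rownames(out) <- NULL
  out
}

#' Per-case vote profile
#'
#' The proportion of observers assigning each category to each case (the
#' stacked-bar-per-case view), with a concordance flag marking cases on which
#' the whole panel agreed.
#'
#' @param m a [score_matrix()].
#' @return data frame with `case_id`, one proportion column per category, and
#'   a logical `concordant` column (`TRUE` iff one proportion equals 1).
#' @export
case_vote_profile <- function(m) {
  stopifnot(inherits(m, "score_matrix"))
  cnt <- count_table(m)
  props <- cnt / ncol(m$scores)
  out <- data.frame(case_id = m$case_ids, props, check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(out) <- c("case_id", m$schema$labels)
  out$concordant <- apply(cnt, 1, max) == ncol(m$scores)
  rownames(out) <- NULL
  out
}

#' Load the deposited multi-institutional HER2 scoring dataset
#'
#' The 460-case by 15-pathologist gastric-cancer HER2 IHC score matrix that
#' motivated this package is publicly deposited at Zenodo
#' (\doi{10.5281/zenodo.18357643}). It is not redistributed with the package;
#' download the CSV and point this loader at it, either via `path` or by
#' setting `options(her2agree.study_data = "<path>")`.
#'
#' @param path path to the downloaded CSV (case by observer layout; use
#'   [read_score_matrix()] directly with `transposed = TRUE` if your copy is
#'   observer by case).
#' @param observer_meta,case_meta optional metadata sidecar paths.
#' @return a [score_matrix()] with N = 460 cases and R = 15 observers.
#' @export
her2_study_scores <- function(path = getOption("her2agree.study_data"),
                              observer_meta = NULL, case_meta = NULL) {
  if (is.null(path) || !file.exists(path %||% "")) {
    stop("the deposited HER2 scoring dataset is not bundled with this ",
         "package; download it from doi:10.5281/zenodo.18357643 and pass ",
         "its path (or set options(her2agree.study_data = ...))")
  }
  m <- read_score_matrix(path, schema = her2_schema(),
                         observer_meta = observer_meta, case_meta = case_meta)
  if (nrow(m$scores) != 460 || ncol(m$scores) != 15)
    warning("expected the 460 x 15 deposited matrix; got ",
            nrow(m$scores), " x ", ncol(m$scores))
  m
}
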