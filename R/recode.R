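#' Category recode map
#'
#' A total mapping from the categories of one schema onto a coarser (or equal)
#' set of output categories. Output categories are ordered by the smallest
#' original code that maps to them and coded 0, 1, ... so that, after a
#' dichotomization, scores enter the ICC as 0/1.
#'
#' @param name map name (used in reports).
#' @param mapping named character vector: original label -> output label.
#' @return an object of class `recode_map`.
#' @examples
#' recode_map("three_cat",
#'            c("0" = "0", "1+" = "low", "2+" = "low", "3+" = "3+"))
#' @export
recode_map <- function(name, mapping) {
  if (is.null(names(mapping)) || any(names(mapping) == ""))
    stop("mapping must be a named vector (original label -> output label)")
  structure(list(name = name,
                 mapping = stats::setNames(as.character(mapping),
                                           names(mapping))),
            class = "recode_map")
}

#' @export
print.recode_map <- function(x, ...) {
  cat("recode map '", x$name, "': ",
      paste(names(x$mapping), "->", x$mapping, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Built-in HER2 recode maps
#'
#' The category merges and clinically motivated dichotomizations used in
#' HER2 IHC concordance reporting, addressable by name:
#' `three_cat` (0 / low / 3+ where low merges 1+ and 2+), the five one-vs-rest
#' splits `0_vs_not0`, `1_vs_not1`, `2_vs_not2`, `low_vs_notlow`, `3_vs_not3`,
#' and the FISH-reflex split `lt2_vs_ge2` (\{0, 1+\} vs \{2+, 3+\}).
#'
#' @param name optional single map name; omit to get the full named list.
#' @return a `recode_map`, or a named list of all of them.
#' @export
her2_recode_maps <- function(name = NULL) {
  maps <- list(
    three_cat   = recode_map("three_cat",
      c("0" = "0", "1+" = "low", "2+" = "low", "3+" = "3+")),
    `0_vs_not0` = recode_map("0_vs_not0",
      c("0" = "0", "1+" = "not 0", "2+" = "not 0", "3+" = "not 0")),
    `1_vs_not1` = recode_map("1_vs_not1",
      c("0" = "not 1+", "1+" = "1+", "2+" = "not 1+", "3+" = "not 1+")),
    `2_vs_not2` = recode_map("2_vs_not2",
      c("0" = "not 2+", "1+" = "not 2+", "2+" = "2+", "3+" = "not 2+")),
    low_vs_notlow = recode_map("low_vs_notlow",
      c("0" = "not low", "1+" = "low", "2+" = "low", "3+" = "not low")),
    `3_vs_not3` = recode_map("3_vs_not3",
      c("0" = "not 3+", "1+" = "not 3+", "2+" = "not 3+", "3+" = "3+")),
    lt2_vs_ge2  = recode_map("lt2_vs_ge2",
      c("0" = "<2+", "1+" = "<2+", "2+" = ">=2+", "3+" = ">=2+"))
  )
  if (is.null(name)) return(maps)
  if (!name %in% names(maps))
    stop("unknown built-in recode map '", name, "'; available: ",
         paste(names(maps), collapse = ", "))
  maps[[name]]
}

#' Apply a recode map to a score matrix
#'
#' @param m a [score_matrix()].
#' @param map a [recode_map()] or the name of a built-in HER2 map.
#' @return a [score_matrix()] over the output schema; case and observer
#'   identifiers and metadata are unchanged.
#' @export
recode <- function(m, map) {
  stopifnot(inherits(m, "score_matrix"))
  if (is.character(map)) map <- her2_recode_maps(map)
  stopifnot(inherits(map, "recode_map"))
  present <- unique(schema_label(m$scores, m$schema))
  unmapped <- setdiff(present, names(map$mapping))
  if (length(unmapped))
    stop("category '", unmapped[1], "' present in matrix but absent from ",
         "recode map '", map$name, "'")
  # output categories ordered by smallest original code mapping to them
  src_codes <- m$schema$codes[match(names(map$mapping), m$schema$labels)]
  keep <- !is.na(src_codes)
  out_labels <- unique(map$mapping[keep][order(src_codes[keep])])
  out_schema <- category_schema(out_labels, seq_along(out_labels) - 1L)
  lut <- stats::setNames(
    out_schema$codes[match(map$mapping, out_schema$labels)],
    names(map$mapping))
  new_scores <- matrix(lut[schema_label(m$scores, m$schema)],
                       nrow = nrow(m$scores))
  score_matrix(new_scores, case_ids = m$case_ids,
               observer_ids = m$observer_ids, schema = out_schema,
               case_meta = m$case_meta, observer_meta = m$observer_meta)
}

#' Select the cases given a score by at least one observer
#'
#' The "X only" subsets of concordance reporting: all cases to which at least
#' one observer assigned the anchor category (or, for a vector anchor such as
#' `c("1+", "2+")`, any of the anchor categories). Scores keep their original
#' categories — subset statistics are computed on the full schema.
#'
#' @param m a [score_matrix()].
#' @param anchor category label(s) or code(s) defining the subset.
#' @return the restricted [score_matrix()].
#' @export
select_subset <- function(m, anchor) {
  stopifnot(inherits(m, "score_matrix"))
  codes <- anchor_codes(m$schema, anchor)
  keep <- rowSums(matrix(m$scores %in% codes, nrow = nrow(m$scores))) > 0
  if (!any(keep))
    stop("no qualifying cases: no observer assigned category '",
         paste(schema_label(codes, m$schema), collapse = "/"), "'")
  score_matrix(m$scores[keep, , drop = FALSE],
               case_ids = m$case_ids[keep], observer_ids = m$observer_ids,
               schema = m$schema,
               case_meta = if (!is.null(m$case_meta)) m$case_meta[keep],
               observer_meta = m$observer_meta)
}

anchor_codes <- function(schema, anchor) {
  codes <- schema_match(as.character(anchor), schema)
  if (anyNA(codes))
    stop("anchor '", anchor[is.na(codes)][1], "' is not a schema category")
  codes
}

#' Rating counts within "at least one observer" subsets
#'
#' For each anchor category, restricts to the cases given that score by at
#' least one observer and tallies every rating in the subset by category
#' (the ratings cross-tabulation of a panel). Row totals equal
#' R x (subset size).
#'
#' @param m a [score_matrix()].
#' @param anchors anchor categories; default all schema categories.
#' @return data frame: `subset`, `n_cases`, one count column per category,
#'   `total_ratings`, and a logical `empty` flag for anchors never assigned.
#' @export
subset_rating_counts <- function(m, anchors = m$schema$labels) {
  stopifnot(inherits(m, "score_matrix"))
  rows <- lapply(anchors, function(a) {
    code <- anchor_codes(m$schema, a)
    keep <- rowSums(matrix(m$scores %in% code, nrow = nrow(m$scores))) > 0
    if (!any(keep)) {
      counts <- rep(0L, n_categories(m$schema))
      data.frame(subset = paste0(a, " only"), n_cases = 0L,
                 rbind(counts), total_ratings = 0L, empty = TRUE,
                 check.names = FALSE)
    } else {
      sub <- m$scores[keep, , drop = FALSE]
      counts <- tabulate(match(sub, m$schema$codes),
                         nbins = n_categories(m$schema))
      data.frame(subset = paste0(a, " only"), n_cases = sum(keep),
                 rbind(counts), total_ratings = length(sub), empty = FALSE,
                 check.names = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  colnames(out) <- c("subset", "n_cases",
                     paste0(m$schema$labels, " counts"), "total_ratings",
                     "empty")
  rownames(out) <- NULL
  out
}

#' Case co-occurrence between score subsets
#'
#' Entry (a, b) counts the cases that received category a from at least one
#' observer and also category b from at least one observer. The matrix is
#' symmetric and its diagonal holds the subset sizes.
#'
#' @param m a [score_matrix()].
#' @param anchors anchor categories; default all schema categories.
#' @return symmetric integer matrix with anchors as dimnames.
#' @export
subset_case_cooccurrence <- function(m, anchors = m$schema$labels) {
  stopifnot(inherits(m, "score_matrix"))
  codes <- vapply(anchors, function(a) anchor_codes(m$schema, a)[1], integer(1))
  got <- vapply(codes, function(code)
    rowSums(matrix(m$scores == code, nrow = nrow(m$scores))) > 0,
    logical(nrow(m$scores)))
  got <- matrix(got, nrow = nrow(m$scores))
  out <- t(got) %*% got
  storage.mode(out) <- "integer"
  dimnames(out) <- list(anchors, anchors)
  out
}
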