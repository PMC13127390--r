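#' Ordered category schema for ordinal scores
#'
#' A schema names the ordered categories a panel may assign and the integer
#' code backing each label. The default is the clinical HER2 IHC scale
#' 0 < 1+ < 2+ < 3+ coded 0..3; the codes are also the numeric values the
#' intraclass correlation uses.
#'
#' @param labels character vector of unique category names, in rank order.
#' @param codes integer codes, strictly increasing, one per label.
#' @return an object of class `category_schema`.
#' @examples
#' her2_schema()
#' category_schema(c("neg", "pos"))
#' @export
category_schema <- function(labels, codes = seq_along(labels) - 1L) {
  labels <- as.character(labels)
  codes <- as.integer(codes)
  if (length(labels) < 2) stop("a schema needs at least 2 categories")
  if (anyDuplicated(labels)) stop("schema labels must be unique")
  if (length(codes) != length(labels)) stop("one code per label required")
  if (any(diff(codes) <= 0)) stop("schema codes must be strictly increasing")
  structure(list(labels = labels, codes = codes), class = "category_schema")
}

#' @rdname category_schema
#' @export
her2_schema <- function() category_schema(c("0", "1+", "2+", "3+"), 0:3)

#' @export
print.category_schema <- function(x, ...) {
  cat("category schema:", paste(x$labels, collapse = " < "),
      sprintf("(codes %s)\n", paste(x$codes, collapse = ",")))
  invisible(x)
}

n_categories <- function(schema) length(schema$labels)

# Map a character vector of tokens (labels or numeric codes, both dialects
# accepted) onto schema codes; NA where the token is unknown.
schema_match <- function(tokens, schema) {
  idx <- match(trimws(tokens), schema$labels)
  num <- suppressWarnings(as.integer(trimws(tokens)))
  idx2 <- match(num, schema$codes)
  out <- schema$codes[idx]
  out[is.na(idx)] <- schema$codes[idx2[is.na(idx)]]
  out
}

schema_label <- function(codes, schema) {
  schema$labels[match(codes, schema$codes)]
}
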