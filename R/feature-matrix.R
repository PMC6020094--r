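#' Feature matrices
#'
#' A `feature_matrix` is a numeric molecules-by-features matrix carrying a
#' `kind` (`"descriptor"` or `"fingerprint"`) and a per-column `family` tag
#' (a descriptor family name or the fingerprint kind). Row names are
#' molecule ids; column names are unique feature names. Matrices never
#' contain missing cells: molecules whose computation fails are excluded
#' before assembly and reported by the producing function.
#'
#' @param values Numeric matrix with row and column names.
#' @param kind `"descriptor"` or `"fingerprint"`.
#' @param family Named character vector tagging every column.
#' @return A `feature_matrix`.
#' @export
feature_matrix <- function(values, kind = c("descriptor", "fingerprint"),
                           family) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values), !is.null(colnames(values)))
  if (anyDuplicated(colnames(values)))
    stop("feature names must be unique")
  if (any(!is.finite(values)))
    stop("feature matrix contains missing or non-finite cells")
  if (kind == "fingerprint" && !all(values %in% c(0, 1)))
    stop("fingerprint values must be 0/1")
  stopifnot(length(family) == ncol(values))
  structure(values, kind = kind, family = setNames(as.character(family),
                                                   colnames(values)),
            class = c("feature_matrix", class(matrix())))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix: %d molecules x %d features (%s)>\n",
              nrow(x), ncol(x), attr(x, "kind")))
  fams <- table(attr(x, "family"))
  cat("  families:", paste(names(fams), fams, sep = ":", collapse = ", "),
      "\n")
  invisible(x)
}

#' Subset a feature matrix by column names, preserving metadata
#'
#' @param fm A [feature_matrix].
#' @param columns Character vector of feature names to keep.
#' @return A `feature_matrix` with the selected columns.
#' @export
fm_select <- function(fm, columns) {
  stopifnot(all(columns %in% colnames(fm)))
  feature_matrix(unclass(fm)[, columns, drop = FALSE], attr(fm, "kind"),
                 attr(fm, "family")[columns])
}

#' Bind two feature matrices on shared rows
#'
#' @param a,b [feature_matrix] objects with identical row ids.
#' @return A combined `feature_matrix` (kind taken from `a`).
#' @export
fm_cbind <- function(a, b) {
  stopifnot(identical(rownames(a), rownames(b)))
  feature_matrix(cbind(unclass(a), unclass(b)), attr(a, "kind"),
                 c(attr(a, "family"), attr(b, "family")))
}

#' Convert a feature matrix to a data frame with an id column
#'
#' @param fm A [feature_matrix].
#' @return A data.frame whose first column `id` holds the row names.
#' @export
fm_as_data_frame <- function(fm) {
  data.frame(id = rownames(fm), unclass(fm), check.names = FALSE,
             row.names = NULL, stringsAsFactors = FALSE)
}
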