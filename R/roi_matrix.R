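#' Construct a subjects-by-ROI morphometry matrix
#'
#' Lightweight container for the feature matrix handed to harmonization and
#' clustering: a numeric matrix (rows = subjects, columns = ROIs) plus the
#' per-column feature kind and a provenance record of every adjustment that has
#' been applied.
#'
#' @param values numeric matrix with row names (subject ids) and column names
#'   (ROI names).
#' @param kind named character vector, `"thickness"` or `"volume"` per column;
#'   defaults to [roi_kind()] looked up by column name.
#' @param adjustments character vector of adjustment tags already applied.
#' @return An object of class `roi_matrix` (a list with elements `values`,
#'   `kind`, `adjustments`).
#' @export
roi_matrix <- function(values, kind = NULL, adjustments = character()) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    stop("`values` must have row names (subject ids)")
  if (is.null(colnames(values)))
    stop("`values` must have column names (ROI names)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate subject ids in `values`")
  if (any(!is.finite(values)))
    stop("missing or non-finite values in ROI matrix")
  if (is.null(kind)) kind <- roi_kind(colnames(values))
  kind <- kind[colnames(values)]
  if (any(is.na(kind)) || !all(kind %in% c("thickness", "volume")))
    stop("`kind` must map every column to 'thickness' or 'volume'")
  structure(list(values = values, kind = kind, adjustments = adjustments),
            class = "roi_matrix")
}

#' @export
print.roi_matrix <- function(x, ...) {
  cat(sprintf("<roi_matrix> %d subjects x %d features (%d thickness, %d volume)\n",
              nrow(x$values), ncol(x$values),
              sum(x$kind == "thickness"), sum(x$kind == "volume")))
  if (length(x$adjustments))
    cat("adjustments:", paste(x$adjustments, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.roi_matrix <- function(x) dim(x$values)

#' Subset the subjects of an roi_matrix
#'
#' @param x an `roi_matrix`.
#' @param subjects subject ids or logical/integer row index.
#' @return An `roi_matrix` restricted to the requested rows.
#' @export
subset_subjects <- function(x, subjects) {
  stopifnot(inherits(x, "roi_matrix"))
  roi_matrix(x$values[subjects, , drop = FALSE], x$kind, x$adjustments)
}

thickness_cols <- function(x) which(x$kind == "thickness")
volume_cols <- function(x) which(x$kind == "volume")
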