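#' Construct a taxon-by-sample abundance table
#'
#' The canonical container of this package: a non-negative integer matrix
#' with taxa as rows and samples as columns, both uniquely named. All
#' downstream operations (diversity, profiling, ordination, habitat
#' classification, networks) consume this class.
#'
#' @param counts numeric matrix (or object coercible to one) of
#'   non-negative integers; rows are taxa, columns are samples.
#' @param taxon_ids optional character vector of row names; defaults to
#'   `rownames(counts)`.
#' @param sample_ids optional character vector of column names; defaults
#'   to `colnames(counts)`.
#' @return an `abundance_table` (an integer matrix with class attribute).
#' @export
#' @examples
#' m <- matrix(c(1, 2, 0, 5, 3, 0), nrow = 3, byrow = TRUE,
#'             dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
#' abundance_table(m)
abundance_table <- function(counts, taxon_ids = NULL, sample_ids = NULL) {
  counts <- as.matrix(counts)
  if (!is.null(taxon_ids)) rownames(counts) <- taxon_ids
  if (!is.null(sample_ids)) colnames(counts) <- sample_ids
  validate_abundance_table(counts)
  storage.mode(counts) <- "integer"
  structure(counts, class = c("abundance_table", class(matrix())))
}

validate_abundance_table <- function(counts) {
  if (length(counts) == 0L || nrow(counts) < 1L)
    stop("abundance table is empty", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("abundance table must have taxon (row) and sample (column) names",
         call. = FALSE)
  rn <- trimws(rownames(counts)); cn <- trimws(colnames(counts))
  rownames(counts) <- rn; colnames(counts) <- cn
  if (anyDuplicated(rn))
    stop("duplicate taxon ID(s): ",
         paste(unique(rn[duplicated(rn)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(cn))
    stop("duplicate sample ID(s): ",
         paste(unique(cn[duplicated(cn)]), collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-integer or negative count at taxon '%s', sample '%s'",
                 rn[bad[1, 1]], cn[bad[1, 2]]), call. = FALSE)
  invisible(counts)
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d taxa x %d samples, %s reads\n",
              nrow(x), ncol(x),
              format(sum(as.numeric(x)), big.mark = ",")))
  utils::str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' Coerce to an abundance table
#' @param x matrix-like object with dimnames.
#' @return an `abundance_table`.
#' @export
as_abundance_table <- function(x) {
  if (inherits(x, "abundance_table")) return(x)
  abundance_table(x)
}

# Drop class for arithmetic while keeping dimnames.
count_matrix <- function(table) {
  m <- unclass(table)
  storage.mode(m) <- "double"
  m
}

#' Sample metadata table
#'
#' Per-sample experimental factors: site, permafrost layer and crude-oil
#' contamination load. Levels are validated against declared domains so a
#' typo in a metadata file fails loudly rather than creating a phantom
#' factor level.
#'
#' @param df data.frame with columns `sample_id`, `site`, `layer`,
#'   `contamination` (further columns are carried along).
#' @param layer_levels,contamination_levels allowed factor levels.
#' @return a validated data.frame of class `sample_metadata`.
#' @export
sample_metadata <- function(df,
                            layer_levels = c("upper", "deeper"),
                            contamination_levels = c("0", "30", "50")) {
  req <- c("sample_id", "site", "layer", "contamination")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$sample_id <- trimws(as.character(df$sample_id))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  df$layer <- as.character(df$layer)
  df$contamination <- as.character(df$contamination)
  if (!all(df$layer %in% layer_levels))
    stop("unknown layer level(s): ",
         paste(setdiff(df$layer, layer_levels), collapse = ", "), call. = FALSE)
  if (!all(df$contamination %in% contamination_levels))
    stop("unknown contamination level(s): ",
         paste(setdiff(df$contamination, contamination_levels), collapse = ", "),
         call. = FALSE)
  # contaminated-vs-not contrast used by the habitat classifier
  df$oiled <- ifelse(df$contamination == "0", "uncontaminated", "contaminated")
  class(df) <- c("sample_metadata", "data.frame")
  df
}

# Align metadata rows to the samples of a table; every sample must appear
# exactly once. Extra metadata rows are allowed (and dropped).
align_metadata <- function(table, metadata) {
  idx <- match(colnames(table), metadata$sample_id)
  if (anyNA(idx))
    stop("sample(s) missing from metadata: ",
         paste(colnames(table)[is.na(idx)], collapse = ", "), call. = FALSE)
  metadata[idx, , drop = FALSE]
}
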