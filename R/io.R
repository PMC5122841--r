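#' Read a taxon abundance table
#'
#' Two on-disk dialects are supported: a plain tab-separated matrix (first
#' column taxon ID, remaining columns one per sample) and the mothur
#' "shared" format (`label`, `Group`, `numOtus` header columns, one row per
#' sample). Whatever the on-disk orientation, the returned table always has
#' taxa as rows; mothur shared input is transposed on read. IDs are kept
#' verbatim apart from trimming leading/trailing whitespace.
#'
#' @param path path to a UTF-8 text file.
#' @param dialect `"tsv_matrix"` or `"mothur_shared"`.
#' @return an [abundance_table()].
#' @export
read_abundance_table <- function(path, dialect = c("tsv_matrix", "mothur_shared")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("empty table in ", path, call. = FALSE)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- trimws(cells[[1]])

  if (dialect == "tsv_matrix") {
    sample_ids <- header[-1]
    if (anyDuplicated(sample_ids))
      stop("duplicate sample ID in header: ",
           paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
           call. = FALSE)
    body <- cells[-1]
    taxon_ids <- trimws(vapply(body, `[`, "", 1L))
    counts <- parse_count_block(body, keep = -1L, n_col = length(sample_ids),
                                row_ids = taxon_ids, col_ids = sample_ids)
    abundance_table(counts, taxon_ids, sample_ids)
  } else {
    fixed <- c("label", "Group", "numOtus")
    if (!identical(tolower(header[1:3]), tolower(fixed)))
      stop("not a mothur shared file (expected label/Group/numOtus header)",
           call. = FALSE)
    otu_ids <- header[-(1:3)]
    if (anyDuplicated(otu_ids))
      stop("duplicate OTU ID in header: ",
           paste(unique(otu_ids[duplicated(otu_ids)]), collapse = ", "),
           call. = FALSE)
    body <- cells[-1]
    sample_ids <- trimws(vapply(body, `[`, "", 2L))
    if (anyDuplicated(sample_ids))
      stop("duplicate sample (Group) ID: ",
           paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
           call. = FALSE)
    counts <- parse_count_block(body, keep = -(1:3), n_col = length(otu_ids),
                                row_ids = sample_ids, col_ids = otu_ids)
    abundance_table(t(counts), otu_ids, sample_ids)
  }
}

# Parse the numeric cells of split lines into a matrix, reporting the
# offending coordinates on failure.
parse_count_block <- function(body, keep, n_col, row_ids, col_ids) {
  n_row <- length(body)
  out <- matrix(0, n_row, n_col, dimnames = list(row_ids, col_ids))
  for (i in seq_len(n_row)) {
    vals <- trimws(body[[i]][keep])
    if (length(vals) != n_col)
      stop(sprintf("row '%s' has %d count field(s); expected %d",
                   row_ids[i], length(vals), n_col), call. = FALSE)
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(is.na(num) | num < 0 | num != round(num))
    if (length(bad))
      stop(sprintf("non-integer count '%s' at row '%s', column '%s'",
                   vals[bad[1]], row_ids[i], col_ids[bad[1]]), call. = FALSE)
    out[i, ] <- num
  }
  out
}

#' Write an abundance table
#'
#' @param table an [abundance_table()].
#' @param path output file path.
#' @param dialect `"tsv_matrix"` or `"mothur_shared"`; for the latter the
#'   mothur `label` column is written as `"asv"` and `numOtus` as the taxon
#'   count.
#' @return invisibly, `path`.
#' @export
write_abundance_table <- function(table, path,
                                  dialect = c("tsv_matrix", "mothur_shared")) {
  dialect <- match.arg(dialect)
  table <- as_abundance_table(table)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (dialect == "tsv_matrix") {
    writeLines(paste(c("taxon_id", colnames(table)), collapse = "\t"), con)
    for (i in seq_len(nrow(table)))
      writeLines(paste(c(rownames(table)[i], table[i, ]), collapse = "\t"), con)
  } else {
    writeLines(paste(c("label", "Group", "numOtus", rownames(table)),
                     collapse = "\t"), con)
    for (j in seq_len(ncol(table)))
      writeLines(paste(c("asv", colnames(table)[j], nrow(table), table[, j]),
                       collapse = "\t"), con)
  }
  invisible(path)
}

#' Read sample metadata
#'
#' Tab-separated, one row per sample, with at least the columns
#' `sample_id`, `site`, `layer`, `contamination`.
#'
#' @param path TSV file path.
#' @param ... passed to [sample_metadata()] (level domains).
#' @return a `sample_metadata` data.frame.
#' @export
read_sample_metadata <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  sample_metadata(df, ...)
}

#' Read a taxonomy lineage map
#'
#' Tab-separated: `taxon_id` plus rank columns ordered coarse to fine
#' (any subset of phylum, class, order, family, genus). Empty cells are
#' unknown ranks and are kept explicit; [aggregate_by_rank()] maps them to
#' an `unclassified_<rank>` bucket.
#'
#' @param path TSV file path.
#' @return data.frame of class `taxonomy_map`.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  taxonomy_map(df)
}

#' Construct/validate a taxonomy map
#' @param df data.frame with `taxon_id` and rank columns.
#' @return data.frame of class `taxonomy_map`.
#' @export
taxonomy_map <- function(df) {
  if (!"taxon_id" %in% names(df))
    stop("taxonomy needs a taxon_id column", call. = FALSE)
  df$taxon_id <- trimws(df$taxon_id)
  if (anyDuplicated(df$taxon_id))
    stop("duplicate taxon_id in taxonomy: ",
         paste(unique(df$taxon_id[duplicated(df$taxon_id)]), collapse = ", "),
         call. = FALSE)
  known <- c("phylum", "class", "order", "family", "genus")
  ranks <- intersect(known, names(df))
  if (!length(ranks)) stop("taxonomy has no recognised rank columns", call. = FALSE)
  attr(df, "ranks") <- ranks
  class(df) <- c("taxonomy_map", "data.frame")
  df
}

#' Aggregate counts to a coarser taxonomic rank
#'
#' Sums counts over taxa sharing a rank label; per-sample totals are
#' conserved exactly. Taxa with an unknown label at the requested rank go
#' into an `unclassified_<rank>` bucket (never silently dropped); taxa
#' absent from the taxonomy do so only when `unclassified_bucket = TRUE`,
#' otherwise they are an error.
#'
#' @param table an [abundance_table()].
#' @param taxonomy a [taxonomy_map()].
#' @param rank one of the taxonomy's rank columns.
#' @param unclassified_bucket allow taxa missing from the taxonomy.
#' @return an [abundance_table()] keyed by rank label.
#' @export
aggregate_by_rank <- function(table, taxonomy, rank, unclassified_bucket = TRUE) {
  table <- as_abundance_table(table)
  ranks <- attr(taxonomy, "ranks")
  if (!rank %in% ranks)
    stop("rank '", rank, "' not in taxonomy (has: ",
         paste(ranks, collapse = ", "), ")", call. = FALSE)
  sentinel <- paste0("unclassified_", rank)
  idx <- match(rownames(table), taxonomy$taxon_id)
  if (anyNA(idx) && !unclassified_bucket)
    stop("taxa missing from taxonomy: ",
         paste(rownames(table)[is.na(idx)], collapse = ", "), call. = FALSE)
  labels <- taxonomy[[rank]][idx]
  labels[is.na(labels) | !nzchar(trimws(labels))] <- sentinel
  agg <- rowsum(count_matrix(table), group = labels)
  agg <- agg[order(rownames(agg)), , drop = FALSE]
  abundance_table(agg)
}
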