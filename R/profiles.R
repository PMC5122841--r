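#' Relative abundance table
#'
#' Column-normalises a count table to per-sample proportions or
#' percentages. No rounding is applied; round only at presentation time.
#'
#' @param table an [abundance_table()] (or matrix with dimnames).
#' @param scale `"fraction"` (columns sum to 1) or `"percent"` (100).
#' @return numeric matrix of class `rel_abundance` with a `scale`
#'   attribute.
#' @export
relative_abundance <- function(table, scale = c("fraction", "percent")) {
  scale <- match.arg(scale)
  m <- if (inherits(table, "abundance_table")) count_matrix(table)
       else as.matrix(table)
  totals <- colSums(m)
  if (any(totals <= 0))
    stop("zero-total sample(s): ",
         paste(colnames(m)[totals <= 0], collapse = ", "), call. = FALSE)
  rel <- sweep(m, 2, totals, "/")
  if (scale == "percent") rel <- rel * 100
  structure(rel, scale = scale, class = c("rel_abundance", class(matrix())))
}

#' Top-k taxa by mean relative abundance
#'
#' Ranks taxa by their mean relative abundance across samples,
#' descending; ties are broken lexicographically by taxon ID so the
#' ranking is deterministic.
#'
#' @param rel a [relative_abundance()] matrix (counts are accepted and
#'   normalised first).
#' @param k how many taxa to return; if larger than the table a warning is
#'   given and all taxa are returned.
#' @return character vector of taxon IDs, best first.
#' @export
top_k_taxa <- function(rel, k) {
  if (!inherits(rel, "rel_abundance")) rel <- relative_abundance(rel)
  stopifnot(k >= 1)
  means <- rowMeans(rel)
  if (k > length(means)) {
    warning("k = ", k, " exceeds the ", length(means), " taxa; returning all")
    k <- length(means)
  }
  ord <- order(-means, rownames(rel))
  rownames(rel)[ord][seq_len(k)]
}

#' Hierarchical structure behind a top-k abundance heatmap
#'
#' Restricts a relative-abundance table to its top-k taxa and clusters
#' both samples (on the chosen sample distance) and taxa (on correlation
#' distance between abundance profiles), the structure underlying a
#' clustered-heatmap figure.
#'
#' @param rel a [relative_abundance()] matrix (or counts, normalised
#'   first).
#' @param k number of top taxa to keep (see [top_k_taxa()]).
#' @param sample_distance `"bray_curtis"` or `"euclidean"`.
#' @param linkage `"average"` or `"complete"`.
#' @return list of class `heatmap_structure` with `taxa` and `samples`
#'   (ordered as in the dendrograms), `sample_tree` and `taxon_tree`
#'   (`hclust` objects).
#' @export
heatmap_structure <- function(rel, k = 50,
                              sample_distance = c("bray_curtis", "euclidean"),
                              linkage = c("average", "complete")) {
  sample_distance <- match.arg(sample_distance)
  linkage <- match.arg(linkage)
  if (!inherits(rel, "rel_abundance")) rel <- relative_abundance(rel)
  if (ncol(rel) < 2) stop("need at least 2 samples to cluster", call. = FALSE)
  top <- top_k_taxa(rel, min(k, nrow(rel)))
  sub <- rel[top, , drop = FALSE]
  d_samp <- switch(sample_distance,
                   bray_curtis = bray_curtis(sub),
                   euclidean = stats::dist(t(sub)))
  sample_tree <- stats::hclust(d_samp, method = linkage)
  taxon_tree <- NULL
  if (length(top) >= 2) {
    # correlation distance between taxon profiles; constant profiles sit at
    # maximal distance from everything
    cc <- suppressWarnings(stats::cor(t(sub)))
    cc[!is.finite(cc)] <- 0
    diag(cc) <- 1
    taxon_tree <- stats::hclust(stats::as.dist(1 - cc), method = linkage)
  }
  structure(list(
    taxa = if (is.null(taxon_tree)) top else top[taxon_tree$order],
    samples = colnames(sub)[sample_tree$order],
    sample_tree = sample_tree, taxon_tree = taxon_tree,
    sample_distance = sample_distance, linkage = linkage),
    class = "heatmap_structure")
}

#' Write a dendrogram as Newick
#'
#' @param tree an `hclust` object (e.g. from [heatmap_structure()]).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_dendrogram <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
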