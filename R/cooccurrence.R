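#' Remove taxa below a mean relative-abundance floor
#'
#' Drops taxa whose mean (across samples) per-sample relative abundance is
#' strictly below the threshold; the default 1e-4 is the conventional
#' 0.01% floor used before network construction. A taxon sitting exactly
#' at the threshold is retained (removal is strictly "less than").
#'
#' @param table an [abundance_table()].
#' @param min_mean_relabund threshold as a fraction (1e-4 = 0.01%).
#' @return the filtered [abundance_table()].
#' @export
filter_rare <- function(table, min_mean_relabund = 1e-4) {
  table <- as_abundance_table(table)
  rel <- relative_abundance(table)
  keep <- rowMeans(rel) >= min_mean_relabund
  if (!any(keep))
    stop("no taxa at or above a mean relative abundance of ",
         min_mean_relabund, "; lower the threshold", call. = FALSE)
  abundance_table(unclass(table)[keep, , drop = FALSE])
}

#' Spearman screen over all taxon pairs
#'
#' Computes Spearman's rho (average ranks for ties) between the abundance
#' profiles of every unordered taxon pair, with a two-sided p-value from
#' the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom (p = 0 at |rho| = 1). A pair passes the screen when
#' `rho > rho_min` and `p < p_max`, both strict - the conventional
#' "robust correlation" rule rho > 0.6, p < 0.01. Pairs where either
#' profile has zero variance have undefined rho and fail, flagged.
#'
#' @param table an [abundance_table()] (typically after [filter_rare()]).
#' @param rho_min minimum rho (exclusive).
#' @param p_max maximum p-value (exclusive).
#' @return data.frame of class `edge_screen`, one row per pair
#'   (`taxon_a < taxon_b` lexicographically): `rho`, `p_value`, `pass`,
#'   `zero_variance`, `n_samples`.
#' @export
spearman_screen <- function(table, rho_min = 0.6, p_max = 0.01) {
  table <- as_abundance_table(table)
  m <- count_matrix(table)
  n <- ncol(m)
  if (n < 4) stop("need at least 4 samples for the Spearman screen",
                  call. = FALSE)
  ord <- order(rownames(m))
  m <- m[ord, , drop = FALSE]
  rho <- suppressWarnings(stats::cor(t(m), method = "spearman"))
  idx <- which(upper.tri(rho), arr.ind = TRUE)
  r <- rho[idx]
  zv <- !is.finite(r)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- ifelse(zv, NA_real_,
              ifelse(abs(r) >= 1, 0, 2 * stats::pt(-abs(tt), df = n - 2)))
  out <- data.frame(taxon_a = rownames(m)[idx[, 1]],
                    taxon_b = rownames(m)[idx[, 2]],
                    rho = ifelse(zv, NA_real_, r), p_value = p,
                    pass = !zv & !is.na(r) & r > rho_min & p < p_max,
                    zero_variance = zv, n_samples = n,
                    stringsAsFactors = FALSE)
  attr(out, "rho_min") <- rho_min
  attr(out, "p_max") <- p_max
  class(out) <- c("edge_screen", "data.frame")
  out
}

#' Construct a co-occurrence network
#'
#' @param nodes character vector of taxon IDs.
#' @param edges data.frame with columns `taxon_a`, `taxon_b`, `e_weight`
#'   and optionally `rho`, `p_value`.
#' @param n_samples number of samples behind the e-weights.
#' @return list of class `cooc_network`.
#' @export
cooc_network <- function(nodes, edges, n_samples) {
  stopifnot(is.character(nodes), !anyDuplicated(nodes))
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  for (col in c("rho", "p_value"))
    if (!col %in% names(edges)) edges[[col]] <- rep(NA_real_, nrow(edges))
  if (nrow(edges)) {
    if (!all(c(edges$taxon_a, edges$taxon_b) %in% nodes))
      stop("edge endpoint not in node set", call. = FALSE)
    if (any(edges$taxon_a == edges$taxon_b))
      stop("self-edges are not allowed", call. = FALSE)
    if (any(edges$e_weight < 0 | edges$e_weight > n_samples))
      stop("e_weight outside [0, n_samples]", call. = FALSE)
    swap <- edges$taxon_a > edges$taxon_b
    tmp <- edges$taxon_a[swap]
    edges$taxon_a[swap] <- edges$taxon_b[swap]
    edges$taxon_b[swap] <- tmp
    edges <- edges[order(edges$taxon_a, edges$taxon_b), , drop = FALSE]
    rownames(edges) <- NULL
    if (anyDuplicated(edges[c("taxon_a", "taxon_b")]))
      stop("duplicate edge", call. = FALSE)
  }
  structure(list(nodes = nodes,
                 edges = edges[c("taxon_a", "taxon_b", "e_weight",
                                 "rho", "p_value")],
                 n_samples = as.integer(n_samples)),
            class = "cooc_network")
}

#' @export
print.cooc_network <- function(x, ...) {
  cat(sprintf("cooc_network: %d nodes, %d edges (over %d samples)\n",
              length(x$nodes), nrow(x$edges), x$n_samples))
  invisible(x)
}

#' Project the taxon-sample affiliation network onto taxa
#'
#' Builds the two-mode (bipartite) incidence of taxa against the samples
#' in which they are detected (`count > min_count`) and projects it onto
#' the taxon mode: an edge joins two taxa detected together in at least
#' one sample, weighted by the number of shared samples (the e-weight).
#' When an [spearman_screen()] result is supplied, only pairs passing the
#' screen become edges, and rho/p annotations are carried onto them; the
#' screened network is always a subgraph of the unscreened projection.
#'
#' @param table an [abundance_table()].
#' @param screen an `edge_screen`, or NULL for the unscreened projection.
#' @param min_count detection floor; presence means `count > min_count`.
#' @return a [cooc_network()] whose node set is all taxa of the table
#'   (taxa sharing no sample remain isolated nodes).
#' @export
project_affiliation <- function(table, screen = NULL, min_count = 0) {
  table <- as_abundance_table(table)
  m <- count_matrix(table)
  pres <- (m > min_count) * 1
  shared <- tcrossprod(pres)  # taxa x taxa shared-sample counts
  idx <- which(upper.tri(shared) & shared >= 1, arr.ind = TRUE)
  edges <- data.frame(taxon_a = rownames(m)[idx[, 1]],
                      taxon_b = rownames(m)[idx[, 2]],
                      e_weight = shared[idx],
                      stringsAsFactors = FALSE)
  if (!is.null(screen)) {
    stopifnot(inherits(screen, "edge_screen"))
    key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
    pass <- screen[screen$pass, , drop = FALSE]
    hit <- match(key(edges$taxon_a, edges$taxon_b),
                 key(pass$taxon_a, pass$taxon_b))
    edges <- edges[!is.na(hit), , drop = FALSE]
    hit <- hit[!is.na(hit)]
    edges$rho <- pass$rho[hit]
    edges$p_value <- pass$p_value[hit]
  }
  cooc_network(rownames(m), edges, ncol(m))
}

#' Induced subnetwork on selected taxa
#'
#' Keeps exactly the listed nodes and every edge joining two of them,
#' weights untouched - the subgraph used to isolate e.g. hydrocarbon-
#' degrader specialists from a meta-community network.
#'
#' @param net a [cooc_network()].
#' @param taxa node subset; unknown names are an error listing them.
#' @return a [cooc_network()].
#' @export
subnetwork <- function(net, taxa) {
  stopifnot(inherits(net, "cooc_network"))
  unknown <- setdiff(taxa, net$nodes)
  if (length(unknown))
    stop("unknown taxa: ", paste(unknown, collapse = ", "), call. = FALSE)
  keep <- net$edges$taxon_a %in% taxa & net$edges$taxon_b %in% taxa
  cooc_network(net$nodes[net$nodes %in% taxa],
               net$edges[keep, , drop = FALSE], net$n_samples)
}

#' Above-median-edge view of a network
#'
#' Retains only edges with e-weight strictly above the median e-weight of
#' the network (even edge counts use the midpoint of the two central
#' values). Nodes are all retained, possibly isolated. This is the "upper
#' half" view used to focus degree analysis on the most frequently
#' co-occurring pairs.
#'
#' @param net a [cooc_network()] with at least one edge.
#' @return a [cooc_network()].
#' @export
upper_half_view <- function(net) {
  stopifnot(inherits(net, "cooc_network"))
  if (nrow(net$edges) == 0)
    stop("network has no edges", call. = FALSE)
  med <- stats::median(net$edges$e_weight)
  cooc_network(net$nodes,
               net$edges[net$edges$e_weight > med, , drop = FALSE],
               net$n_samples)
}

#' Per-node connection and strongest-pair summaries
#'
#' For each node: the number of distinct co-occurring partners, the
#' maximal incident e-weight, and all partners achieving it (ties listed,
#' sorted lexicographically and comma-joined) - the column layout of a
#' keystone-taxon table. Rows are sorted by strongest e-weight
#' (descending), then connections (descending), then node name.
#'
#' @param net a [cooc_network()].
#' @return data.frame with `taxon`, `connections`, `strongest_partners`,
#'   `strongest_e_weight` (NA for isolated nodes).
#' @export
node_summaries <- function(net) {
  stopifnot(inherits(net, "cooc_network"))
  if (!length(net$nodes)) stop("empty node set", call. = FALSE)
  e <- net$edges
  rows <- lapply(net$nodes, function(v) {
    inc <- e[e$taxon_a == v | e$taxon_b == v, , drop = FALSE]
    if (nrow(inc) == 0)
      return(data.frame(taxon = v, connections = 0L,
                        strongest_partners = "",
                        strongest_e_weight = NA_real_,
                        stringsAsFactors = FALSE))
    partners <- ifelse(inc$taxon_a == v, inc$taxon_b, inc$taxon_a)
    w_max <- max(inc$e_weight)
    best <- sort(partners[inc$e_weight == w_max])
    data.frame(taxon = v, connections = length(unique(partners)),
               strongest_partners = paste(best, collapse = ", "),
               strongest_e_weight = w_max, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-ifelse(is.na(out$strongest_e_weight), -Inf,
                           out$strongest_e_weight),
                   -out$connections, out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Chord-diagram adjacency matrix
#'
#' The symmetric non-negative integer matrix of e-weights with zero
#' diagonal; a row sum is the node's total amount of co-occurrence, i.e.
#' its sector width in a chord diagram.
#'
#' @param net a [cooc_network()].
#' @return numeric matrix, nodes x nodes.
#' @export
chord_matrix <- function(net) {
  stopifnot(inherits(net, "cooc_network"))
  if (!length(net$nodes)) stop("empty node set", call. = FALSE)
  m <- matrix(0, length(net$nodes), length(net$nodes),
              dimnames = list(net$nodes, net$nodes))
  e <- net$edges
  if (nrow(e)) {
    m[cbind(e$taxon_a, e$taxon_b)] <- e$e_weight
    m[cbind(e$taxon_b, e$taxon_a)] <- e$e_weight
  }
  m
}

#' Convert a co-occurrence network to igraph
#'
#' @param net a [cooc_network()].
#' @return an undirected `igraph` graph with `weight` (= e-weight),
#'   `rho` and `p_value` edge attributes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "cooc_network"))
  g <- igraph::graph_from_data_frame(
    net$edges[c("taxon_a", "taxon_b")], directed = FALSE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE))
  igraph::E(g)$weight <- net$edges$e_weight
  igraph::E(g)$rho <- net$edges$rho
  igraph::E(g)$p_value <- net$edges$p_value
  g
}

#' Write a co-occurrence network to disk
#'
#' The edge-list TSV has columns `taxon_a`, `taxon_b`, `e_weight`, `rho`,
#' `p_value`, each undirected edge written once with lexicographically
#' ordered endpoints; GraphML (via igraph) carries the same attributes.
#'
#' @param net a [cooc_network()].
#' @param path output file.
#' @param format `"edge_list_tsv"` or `"graphml"`.
#' @return invisibly, `path`.
#' @export
write_network <- function(net, path, format = c("edge_list_tsv", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "cooc_network"))
  if (format == "edge_list_tsv") {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  } else {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  }
  invisible(path)
}

#' Read an edge-list TSV back into a network
#'
#' Inverse of [write_network()] for the TSV format. The node set is the
#' set of edge endpoints (isolated nodes are not representable in a bare
#' edge list); `n_samples` defaults to the maximum e-weight unless given.
#'
#' @param path edge-list TSV path.
#' @param n_samples sample count behind the e-weights.
#' @return a [cooc_network()].
#' @export
read_network <- function(path, n_samples = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  e <- utils::read.delim(path, stringsAsFactors = FALSE)
  nodes <- sort(unique(c(e$taxon_a, e$taxon_b)))
  if (is.null(n_samples))
    n_samples <- if (nrow(e)) max(e$e_weight) else 0L
  cooc_network(nodes, e, n_samples)
}
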