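#' Bray-Curtis dissimilarity between samples
#'
#' `BC_jk = sum_i |x_ij - x_ik| / sum_i (x_ij + x_ik)`: 0 for identical
#' samples, 1 for samples with disjoint taxon support. Works on raw counts
#' or relative abundances.
#'
#' @param table an [abundance_table()], [relative_abundance()] matrix, or
#'   plain taxa-by-samples matrix.
#' @return a `dist` object over samples with entries in `[0, 1]`.
#' @export
bray_curtis <- function(table) {
  m <- if (inherits(table, "abundance_table")) count_matrix(table)
       else as.matrix(table)
  if (ncol(m) < 2) stop("need at least 2 samples", call. = FALSE)
  totals <- colSums(m)
  if (any(totals <= 0))
    stop("zero-total sample(s): ",
         paste(colnames(m)[totals <= 0], collapse = ", "), call. = FALSE)
  num <- stats::dist(t(m), method = "manhattan")
  den <- as.matrix(outer(totals, totals, "+"))
  d <- as.matrix(num) / den
  stats::as.dist(d)
}

#' Principal coordinates analysis
#'
#' Classical metric scaling: squared dissimilarities are Gower
#' double-centred (`B = -1/2 * J D^2 J`) and eigendecomposed. Negative
#' eigenvalues (possible for semi-metric input such as Bray-Curtis) are
#' reported but excluded from axes and from "proportion explained".
#'
#' @param d a `dist` object or symmetric zero-diagonal matrix.
#' @return list of class `pcoa_result`: `coordinates` (samples x axes,
#'   one column per positive eigenvalue), `eigenvalues` (all, decreasing),
#'   `prop_explained` (over positive eigenvalues only).
#' @export
pcoa <- function(d) {
  dm <- as_distance_matrix(d)
  n <- nrow(dm)
  b <- -0.5 * dm^2
  # J A J: row-centering then column-centering of the centred matrix
  b <- sweep(b, 1, rowMeans(b))
  b <- sweep(b, 2, colMeans(b))
  eig <- eigen((b + t(b)) / 2, symmetric = TRUE)
  pos <- which(eig$values > max(eig$values[1], 0) * 1e-12 & eig$values > 0)
  if (length(pos)) {
    coords <- eig$vectors[, pos, drop = FALSE] %*%
      diag(sqrt(eig$values[pos]), length(pos))
    dimnames(coords) <- list(rownames(dm), paste0("PCo", seq_along(pos)))
  } else {
    coords <- matrix(numeric(0), n, 0, dimnames = list(rownames(dm), NULL))
  }
  structure(list(
    coordinates = coords,
    eigenvalues = eig$values,
    prop_explained = if (length(pos)) eig$values[pos] / sum(eig$values[pos])
                     else numeric(0)),
    class = "pcoa_result")
}

as_distance_matrix <- function(d) {
  dm <- if (inherits(d, "dist")) as.matrix(d) else as.matrix(d)
  if (nrow(dm) != ncol(dm) || any(abs(dm - t(dm)) > 1e-8))
    stop("distance matrix must be symmetric", call. = FALSE)
  if (any(abs(diag(dm)) > 1e-12))
    stop("distance matrix must have a zero diagonal", call. = FALSE)
  if (is.null(rownames(dm)))
    rownames(dm) <- colnames(dm) <- paste0("s", seq_len(nrow(dm)))
  dm
}

#' One-factor PERMANOVA
#'
#' Permutational multivariate analysis of variance on a dissimilarity
#' matrix: partitions the total sum of squared dissimilarities
#' (`SS_total = sum_{i<j} d_ij^2 / N`) into among- and within-group parts,
#' forms the pseudo-F `(SS_A / (a - 1)) / (SS_W / (N - a))`, and assesses
#' it by permuting group labels over samples. Permuted statistics tying
#' the observed one count toward the numerator (conservative), so
#' `p = (1 + #[F_perm >= F_obs]) / (1 + n_perm)` with resolution
#' `1 / (n_perm + 1)`. When groups are exact duplicates (`SS_W = 0`) the
#' statistic is `+Inf` and `p` follows from permutation ties.
#'
#' @param d a `dist` or symmetric zero-diagonal matrix.
#' @param groups factor (or vector) of group labels, one per sample, with
#'   at least 2 levels present.
#' @param n_perm number of label permutations (default 999).
#' @param seed optional integer; identical seeds give identical p-values.
#' @return list of class `permanova_result`: `f`, `r_squared`, `p_value`,
#'   `n_perm`, and the partition table `ss` (among/within/total with df).
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL) {
  dm <- as_distance_matrix(d)
  n <- nrow(dm)
  groups <- as.character(groups)
  if (length(groups) != n)
    stop("groups must have one label per sample", call. = FALSE)
  lev <- unique(groups)
  a <- length(lev)
  if (a < 2) stop("need at least 2 groups", call. = FALSE)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  d2 <- dm^2

  ss_within_for <- function(g) {
    sw <- 0
    for (l in unique(g)) {
      idx <- which(g == l)
      if (length(idx) > 1)
        sw <- sw + sum(d2[idx, idx]) / (2 * length(idx))
    }
    sw
  }
  ss_total <- sum(d2) / (2 * n)
  ss_within <- ss_within_for(groups)
  ss_among <- ss_total - ss_within
  f_stat <- function(sa, sw) {
    if (sw <= 1e-12) { if (sa > 1e-12) Inf else NaN }
    else (sa / (a - 1)) / (sw / (n - a))
  }
  f_obs <- f_stat(ss_among, ss_within)

  perm_f <- local_seed(if (is.null(seed)) derive_seed(sum(utf8ToInt(
    paste(groups, collapse = ""))), "permanova") else seed, {
    vapply(seq_len(n_perm), function(i) {
      g <- sample(groups)
      sw <- ss_within_for(g)
      f_stat(ss_total - sw, sw)
    }, numeric(1))
  })
  p <- (1 + sum(perm_f >= f_obs, na.rm = TRUE)) / (1 + n_perm)

  structure(list(
    f = f_obs,
    r_squared = ss_among / ss_total,
    p_value = p,
    n_perm = n_perm,
    ss = data.frame(term = c("among", "within", "total"),
                    ss = c(ss_among, ss_within, ss_total),
                    df = c(a - 1, n - a, n - 1))),
    class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g, R2 = %.4f, p = %.4g (%d permutations)\n",
              x$f, x$r_squared, x$p_value, x$n_perm))
  print(x$ss, row.names = FALSE)
  invisible(x)
}
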