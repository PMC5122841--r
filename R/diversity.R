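#' Shannon diversity
#'
#' `H = -sum(p_i * log(p_i))` over proportions `p_i` of positive counts.
#' Natural log by default (nats); `base = 2` gives bits.
#'
#' @param counts non-negative integer vector of one sample.
#' @param base logarithm base.
#' @return Shannon index, in `[0, log(S_obs)]`.
#' @export
#' @examples
#' shannon(c(25, 25, 25, 25))  # log(4)
shannon <- function(counts, base = exp(1)) {
  counts <- check_counts(counts)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p, base = base))
}

#' Chao1 richness estimator
#'
#' Bias-corrected by default: `S_obs + F1 * (F1 - 1) / (2 * (F2 + 1))`,
#' finite even without doubletons. The classical form
#' `S_obs + F1^2 / (2 * F2)` is available behind a flag (and is `Inf` when
#' `F2 = 0` but singletons exist).
#'
#' @param counts non-negative integer vector.
#' @param bias_corrected use the bias-corrected form (default).
#' @return estimated richness, `>= S_obs`.
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  counts <- check_counts(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected) s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  else if (f1 == 0) s_obs
  else s_obs + f1^2 / (2 * f2)
}

#' ACE richness estimator
#'
#' Abundance-based coverage estimator with the conventional rare/abundant
#' split at `rare_cutoff` reads:
#' `ACE = S_abund + S_rare / C_ace + (F1 / C_ace) * gamma^2`,
#' where `C_ace = 1 - F1 / N_rare` is the sample coverage of the rare
#' group and `gamma^2` its squared coefficient of variation (floored at
#' 0). When every rare individual is a singleton (`C_ace = 0`), or the
#' rare group is a single read, the estimator is undefined and falls back
#' to [chao1()].
#'
#' @param counts non-negative integer vector.
#' @param rare_cutoff counts `<=` this value form the rare group.
#' @return estimated richness.
#' @export
ace <- function(counts, rare_cutoff = 10) {
  counts <- check_counts(counts)
  pos <- counts[counts > 0]
  rare <- pos[pos <= rare_cutoff]
  s_abund <- sum(pos > rare_cutoff)
  s_rare <- length(rare)
  if (s_rare == 0) return(as.numeric(s_abund))
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  c_ace <- 1 - f1 / n_rare
  if (c_ace <= 0 || n_rare <= 1) return(chao1(counts))
  fk <- tabulate(rare, nbins = rare_cutoff)
  k <- seq_len(rare_cutoff)
  gamma2 <- max(s_rare / c_ace * sum(k * (k - 1) * fk) /
                  (n_rare * (n_rare - 1)) - 1, 0)
  s_abund + s_rare / c_ace + f1 / c_ace * gamma2
}

#' Exact rarefaction curve
#'
#' Expected richness in a without-replacement subsample of `n` reads,
#' by the hypergeometric closed form
#' `E[S_n] = sum_i (1 - choose(N - N_i, n) / choose(N, n))`,
#' evaluated in log-gamma arithmetic so large depths do not overflow.
#'
#' @param counts non-negative integer vector.
#' @param grid subsample sizes, each in `[1, sum(counts)]`; default is 25
#'   points evenly spaced up to full depth.
#' @return data.frame with columns `n` and `expected_richness`
#'   (non-decreasing in `n`; equals `S_obs` at `n = N`).
#' @export
rarefaction_curve <- function(counts, grid = NULL) {
  counts <- check_counts(counts)
  n_total <- sum(counts)
  if (is.null(grid))
    grid <- unique(pmax(1, round(seq(1, n_total, length.out = 25))))
  grid <- as.numeric(grid)
  if (any(grid < 1 | grid > n_total))
    stop("subsample sizes must lie in [1, ", n_total, "]", call. = FALSE)
  ni <- counts[counts > 0]
  es <- vapply(grid, function(n) {
    # P(taxon i absent) = C(N - N_i, n) / C(N, n); zero when N - N_i < n
    log_absent <- lchoose(n_total - ni, n) - lchoose(n_total, n)
    sum(1 - exp(log_absent))
  }, numeric(1))
  data.frame(n = grid, expected_richness = es)
}

#' Per-sample alpha-diversity report
#'
#' Observed richness, Shannon, Chao1 and ACE for every sample of a table,
#' plus (optionally) rarefaction curves in long format.
#'
#' @param table an [abundance_table()].
#' @param curve_points number of rarefaction grid points per sample
#'   (0 to skip curves).
#' @param rare_cutoff passed to [ace()].
#' @return list with `indices` (one row per sample) and `curves`
#'   (long-format data.frame, or NULL).
#' @export
diversity_report <- function(table, curve_points = 25, rare_cutoff = 10) {
  table <- as_abundance_table(table)
  m <- count_matrix(table)
  idx <- data.frame(
    sample_id = colnames(m),
    reads = colSums(m),
    s_obs = colSums(m > 0),
    shannon = apply(m, 2, shannon),
    chao1 = apply(m, 2, chao1),
    ace = apply(m, 2, ace, rare_cutoff = rare_cutoff),
    row.names = NULL)
  curves <- NULL
  if (curve_points > 0) {
    curves <- do.call(rbind, lapply(colnames(m), function(s) {
      grid <- unique(pmax(1, round(seq(1, sum(m[, s]),
                                       length.out = curve_points))))
      cbind(sample_id = s, rarefaction_curve(m[, s], grid))
    }))
  }
  list(indices = idx, curves = curves)
}

check_counts <- function(counts) {
  counts <- as.numeric(counts)
  if (any(!is.finite(counts) | counts < 0 | counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (sum(counts) <= 0) stop("all counts are zero", call. = FALSE)
  counts
}
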