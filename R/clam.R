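#' Pool a count table into two habitat groups
#'
#' Sums each taxon's counts within the two levels of a metadata factor
#' (e.g. contaminated vs uncontaminated soil, or upper vs deeper
#' permafrost layer), producing the per-taxon `(y_A, y_B)` input of the
#' multinomial habitat classification. Also records the habitat totals and
#' singleton counts needed for Good-Turing coverage adjustment.
#'
#' @param table an [abundance_table()].
#' @param metadata a [sample_metadata()] covering every sample.
#' @param habitat_factor metadata column with exactly two levels among the
#'   table's samples (e.g. `"oiled"` or `"layer"`).
#' @return list of class `clam_input`: `taxon_id`, `y_a`, `y_b`, habitat
#'   `levels` (A = first sorted level), totals `n_a`, `n_b`, singleton
#'   counts `f1_a`, `f1_b`.
#' @export
pool_by_habitat <- function(table, metadata, habitat_factor) {
  table <- as_abundance_table(table)
  meta <- align_metadata(table, metadata)
  if (!habitat_factor %in% names(meta))
    stop("no metadata column '", habitat_factor, "'", call. = FALSE)
  fac <- as.character(meta[[habitat_factor]])
  lev <- sort(unique(fac))
  if (length(lev) != 2)
    stop("habitat factor '", habitat_factor, "' has ", length(lev),
         " level(s) among these samples; need exactly 2", call. = FALSE)
  m <- count_matrix(table)
  y_a <- rowSums(m[, fac == lev[1], drop = FALSE])
  y_b <- rowSums(m[, fac == lev[2], drop = FALSE])
  structure(list(taxon_id = rownames(m), y_a = y_a, y_b = y_b,
                 levels = lev, n_a = sum(y_a), n_b = sum(y_b),
                 f1_a = sum(y_a == 1), f1_b = sum(y_b == 1)),
            class = "clam_input")
}

#' Construct a CLAM input directly from pooled counts
#'
#' @param y_a,y_b pooled per-taxon counts in habitats A and B.
#' @param taxon_id optional taxon names.
#' @param levels habitat labels, A first.
#' @param n_a,n_b habitat totals; default the vector sums, but can be set
#'   explicitly when the vectors are a subset of a larger pooled table.
#' @return a `clam_input` list, with singleton counts derived from the
#'   vectors.
#' @export
clam_input <- function(y_a, y_b, taxon_id = NULL,
                       levels = c("A", "B"),
                       n_a = sum(y_a), n_b = sum(y_b)) {
  stopifnot(length(y_a) == length(y_b), all(y_a >= 0), all(y_b >= 0),
            n_a >= 0, n_b >= 0)
  if (is.null(taxon_id)) taxon_id <- sprintf("taxon_%d", seq_along(y_a))
  structure(list(taxon_id = taxon_id, y_a = as.numeric(y_a),
                 y_b = as.numeric(y_b), levels = levels,
                 n_a = n_a, n_b = n_b,
                 f1_a = sum(y_a == 1), f1_b = sum(y_b == 1)),
            class = "clam_input")
}

#' Multinomial habitat specialist/generalist classification
#'
#' Classifies each taxon into one of four categories - specialist for
#' habitat A, specialist for habitat B, generalist, or too rare to
#' classify with confidence - by exact one-sided binomial tests on its
#' pooled count split `(y_A, y_B)`, following the supermajority-threshold
#' multinomial classification scheme.
#'
#' With specialization threshold `K` (default 2/3) and sampling-effort-
#' adjusted boundary probabilities
#' `p_A* = K N_A / (K N_A + (1-K) N_B)` and
#' `p_B* = (1-K) N_A / ((1-K) N_A + K N_B)`,
#' four exact binomial tails on `y_A` given `t = y_A + y_B` are evaluated
#' at level `alpha`:
#' * `T_A`: `P(Y >= y_A | t, p_A*) <= alpha` - A-share significantly
#'   above `K` (A-specialist evidence);
#' * `T_B`: `P(Y <= y_A | t, p_B*) <= alpha` - A-share significantly
#'   below `1-K` (B-specialist evidence);
#' * `U_A`: `P(Y <= y_A | t, p_A*) <= alpha` - A-share significantly
#'   below `K`;
#' * `U_B`: `P(Y >= y_A | t, p_B*) <= alpha` - A-share significantly
#'   above `1-K`.
#' A taxon is `specialist_a` if `T_A` rejects, `specialist_b` if `T_B`
#' rejects, `generalist` if both `U_A` and `U_B` reject (its habitat share
#' is confidently inside `(1-K, K)`), and `too_rare` otherwise. Taxa with
#' `t = 0` are excluded (category `absent`).
#'
#' Coverage handling: a habitat count at or below `coverage_limit` is
#' first multiplied by that habitat's Good-Turing sample coverage
#' `C_h = 1 - f1_h / N_h` and rounded half-up to an integer, discounting
#' sparse counts in under-sampled habitats before testing.
#'
#' @param input a `clam_input` from [pool_by_habitat()] or
#'   [clam_input()].
#' @param threshold specialization threshold `K` in `(0.5, 1)`.
#' @param alpha per-test level in `(0, 0.5)`; the default `0.05/20`
#'   mirrors the reference implementation's default.
#' @param coverage_limit counts `<=` this are coverage-adjusted
#'   (0 disables adjustment).
#' @return data.frame of class `clam_result`: taxon, raw and adjusted
#'   counts, the four tail p-values, and `category`.
#' @export
clam_classify <- function(input, threshold = 2/3, alpha = 0.05 / 20,
                          coverage_limit = 30) {
  stopifnot(inherits(input, "clam_input"))
  if (input$n_a <= 0 || input$n_b <= 0)
    stop("both habitat totals must be positive", call. = FALSE)
  if (alpha <= 0 || alpha >= 0.5)
    stop("alpha must be in (0, 0.5)", call. = FALSE)
  if (threshold <= 0.5 || threshold >= 1)
    stop("specialization threshold must be in (0.5, 1)", call. = FALSE)

  cov_a <- 1 - input$f1_a / input$n_a
  cov_b <- 1 - input$f1_b / input$n_b
  adj_a <- input$y_a
  adj_b <- input$y_b
  if (coverage_limit > 0) {
    low_a <- input$y_a > 0 & input$y_a <= coverage_limit
    low_b <- input$y_b > 0 & input$y_b <= coverage_limit
    adj_a[low_a] <- round_half_up(input$y_a[low_a] * cov_a)
    adj_b[low_b] <- round_half_up(input$y_b[low_b] * cov_b)
  }

  dec <- clam_decide(adj_a, adj_b, input$n_a, input$n_b, threshold, alpha)
  category <- dec$category
  category[input$y_a + input$y_b == 0] <- "absent"

  out <- data.frame(taxon_id = input$taxon_id,
                    y_a = input$y_a, y_b = input$y_b,
                    adj_a = adj_a, adj_b = adj_b,
                    p_spec_a = dec$p_spec_a, p_spec_b = dec$p_spec_b,
                    p_below_k = dec$p_below_k, p_above_1mk = dec$p_above_1mk,
                    category = category,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "levels") <- input$levels
  attr(out, "params") <- list(threshold = threshold, alpha = alpha,
                              coverage_limit = coverage_limit,
                              n_a = input$n_a, n_b = input$n_b)
  class(out) <- c("clam_result", "data.frame")
  out
}

# Vectorised decision rules on (possibly adjusted) counts.
clam_decide <- function(y_a, y_b, n_a, n_b, k, alpha) {
  t <- y_a + y_b
  p_a <- k * n_a / (k * n_a + (1 - k) * n_b)
  p_b <- (1 - k) * n_a / ((1 - k) * n_a + k * n_b)
  upper_tail <- function(y, p) ifelse(t > 0, stats::pbinom(y - 1, t, p,
                                                           lower.tail = FALSE), 1)
  lower_tail <- function(y, p) ifelse(t > 0, stats::pbinom(y, t, p), 1)
  p_spec_a <- upper_tail(y_a, p_a)   # T_A
  p_spec_b <- lower_tail(y_a, p_b)   # T_B
  p_below_k <- lower_tail(y_a, p_a)  # U_A
  p_above_1mk <- upper_tail(y_a, p_b)  # U_B
  category <- rep("too_rare", length(t))
  category[p_below_k <= alpha & p_above_1mk <= alpha] <- "generalist"
  category[p_spec_a <= alpha] <- "specialist_a"
  category[p_spec_b <= alpha] <- "specialist_b"
  # with K > 0.5 and alpha < 0.5 both specialist tests cannot reject at
  # once; guard anyway so a pathological input degrades conservatively
  category[p_spec_a <= alpha & p_spec_b <= alpha] <- "too_rare"
  list(category = category, p_spec_a = p_spec_a, p_spec_b = p_spec_b,
       p_below_k = p_below_k, p_above_1mk = p_above_1mk)
}

#' Summarise a CLAM classification
#'
#' Category counts and percentages at the taxon level and weighted by
#' reads (pooled counts), formatted in the "X% (n out of N)" reporting
#' style. Percentages are rounded half-up to two decimals and always
#' recompute from the printed counts.
#'
#' @param result a `clam_result` from [clam_classify()].
#' @return list of class `clam_summary` with data.frames `taxa` and
#'   `reads` (columns: category, count, total, pct, label).
#' @export
clam_summary <- function(result) {
  stopifnot(inherits(result, "clam_result"))
  kept <- result[result$category != "absent", , drop = FALSE]
  if (nrow(kept) == 0) stop("no classified taxa", call. = FALSE)
  cats <- c("specialist_a", "specialist_b", "generalist", "too_rare")
  taxa_n <- vapply(cats, function(cc) sum(kept$category == cc), numeric(1))
  reads_n <- vapply(cats, function(cc)
    sum(kept$y_a[kept$category == cc] + kept$y_b[kept$category == cc]),
    numeric(1))
  mk <- function(counts) {
    total <- sum(counts)
    data.frame(category = cats, count = counts, total = total,
               pct = pct_half_up(counts, total),
               label = format_percent(counts, total),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  structure(list(taxa = mk(taxa_n), reads = mk(reads_n),
                 levels = attr(result, "levels"),
                 n_absent = sum(result$category == "absent")),
            class = "clam_summary")
}

#' @export
print.clam_summary <- function(x, ...) {
  lev <- x$levels %||% c("A", "B")
  cat("Habitat classification (A =", lev[1], ", B =", lev[2], ")\n")
  cat("By taxa:\n")
  for (i in seq_len(nrow(x$taxa)))
    cat(sprintf("  %-22s %s\n", x$taxa$category[i], x$taxa$label[i]))
  cat("By reads:\n")
  for (i in seq_len(nrow(x$reads)))
    cat(sprintf("  %-22s %s\n", x$reads$category[i], x$reads$label[i]))
  if (x$n_absent > 0)
    cat(sprintf("  (%d taxa absent from both habitats excluded)\n", x$n_absent))
  invisible(x)
}

#' Scatter coordinates for a specialist classification plot
#'
#' The conventional visualisation places each taxon at
#' `(y_A + 1, y_B + 1)` on log axes so zero-count taxa remain plottable;
#' specialists for either habitat fall on the flanks, generalists in the
#' middle, rare taxa near the origin.
#'
#' @param result a `clam_result`.
#' @return data.frame with `taxon_id`, `x` (`y_a + 1`), `y` (`y_b + 1`),
#'   `category`.
#' @export
clam_plot_coords <- function(result) {
  stopifnot(inherits(result, "clam_result"))
  data.frame(taxon_id = result$taxon_id, x = result$y_a + 1,
             y = result$y_b + 1, category = result$category,
             stringsAsFactors = FALSE)
}
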