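# Small in-code fixtures and independent oracles shared across tests.

tiny_counts <- function() {
  matrix(c(1, 2,
           0, 5,
           3, 0), nrow = 3, byrow = TRUE,
         dimnames = list(c("taxA", "taxB", "taxC"), c("s1", "s2")))
}

random_table <- function(n_taxa, n_samples, seed, lambda = 20) {
  set.seed(seed)
  m <- matrix(rpois(n_taxa * n_samples, lambda), n_taxa, n_samples,
              dimnames = list(sprintf("t%03d", seq_len(n_taxa)),
                              sprintf("s%02d", seq_len(n_samples))))
  abundance_table(m)
}

two_habitat_metadata <- function(sample_ids, n_contaminated) {
  n <- length(sample_ids)
  sample_metadata(data.frame(
    sample_id = sample_ids,
    site = rep("WN", n),
    layer = rep("upper", n),
    contamination = c(rep("30", n_contaminated),
                      rep("0", n - n_contaminated)),
    stringsAsFactors = FALSE))
}

# Independent CLAM oracle: binomial tails by forward pmf recursion and
# cumulative summation (no pbinom), then the four-test decision rule.
# Returns the category for every y_a in 0:t at once.
oracle_clam_categories <- function(t, n_a, n_b, k, alpha) {
  p_a <- k * n_a / (k * n_a + (1 - k) * n_b)
  p_b <- (1 - k) * n_a / ((1 - k) * n_a + k * n_b)
  pmf <- function(p) {
    f <- numeric(t + 1)
    f[1] <- (1 - p)^t
    if (t > 0)
      for (j in 0:(t - 1))
        f[j + 2] <- f[j + 1] * (p / (1 - p)) * ((t - j) / (j + 1))
    f
  }
  fa <- pmf(p_a); fb <- pmf(p_b)
  lower_a <- cumsum(fa);              lower_b <- cumsum(fb)
  upper_a <- rev(cumsum(rev(fa)));    upper_b <- rev(cumsum(rev(fb)))
  t_a <- upper_a <= alpha   # P(Y >= y | p_a*)
  t_b <- lower_b <= alpha   # P(Y <= y | p_b*)
  u_a <- lower_a <= alpha
  u_b <- upper_b <= alpha
  cat <- rep("too_rare", t + 1)
  cat[u_a & u_b] <- "generalist"
  cat[t_a] <- "specialist_a"
  cat[t_b] <- "specialist_b"
  cat[t_a & t_b] <- "too_rare"
  cat
}

# classify a whole 0:t sweep through the package (coverage adjustment off)
classify_sweep <- function(t, n_a, n_b, k, alpha) {
  y_a <- 0:t
  inp <- clam_input(y_a, t - y_a, n_a = n_a, n_b = n_b)
  clam_classify(inp, threshold = k, alpha = alpha, coverage_limit = 0)$category
}
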