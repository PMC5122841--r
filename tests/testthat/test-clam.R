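test_that("pool_by_habitat sums counts and conserves totals", {
  m <- matrix(c(1, 2, 3, 4,
                0, 0, 5, 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("t1", "t2"),
                              c("c1", "c2", "u1", "u2")))
  tab <- abundance_table(m)
  md <- two_habitat_metadata(colnames(m), n_contaminated = 2)
  ci <- pool_by_habitat(tab, md, "oiled")
  # level A = "contaminated" (alphabetically first)
  expect_identical(ci$levels, c("contaminated", "uncontaminated"))
  expect_equal(unname(ci$y_a), c(3, 0))
  expect_equal(unname(ci$y_b), c(7, 10))
  expect_equal(ci$n_a + ci$n_b, sum(m))

  rt <- random_table(50, 8, seed = 3)
  md8 <- two_habitat_metadata(colnames(rt), 4)
  ci8 <- pool_by_habitat(rt, md8, "oiled")
  expect_equal(ci8$n_a + ci8$n_b, sum(unclass(rt)))

  md_one <- two_habitat_metadata(colnames(rt), 0)
  expect_error(pool_by_habitat(rt, md_one, "oiled"), "exactly 2")
})

test_that("classification matches closed-form binomial tails", {
  # overwhelming one-sided count: P(Y >= 100 | 100, 2/3) = (2/3)^100 << alpha
  r1 <- clam_classify(clam_input(100, 0, n_a = 1000, n_b = 1000),
                      coverage_limit = 0, alpha = 0.005)
  expect_identical(r1$category, "specialist_a")
  expect_equal(r1$p_spec_a, (2 / 3)^100)

  # a doubleton split 1/1 cannot reach significance in any of the 4 tests
  r2 <- clam_classify(clam_input(1, 1, n_a = 1000, n_b = 1000),
                      coverage_limit = 0, alpha = 0.005)
  expect_identical(r2$category, "too_rare")

  # balanced abundant taxon: both U tests reject, both T tests fail
  r3 <- clam_classify(clam_input(500, 500, n_a = 5000, n_b = 5000),
                      coverage_limit = 0, alpha = 0.005)
  expect_identical(r3$category, "generalist")
  expect_gt(r3$p_spec_a, 0.005)
  expect_gt(r3$p_spec_b, 0.005)

  # taxon absent from both habitats is flagged, not classified
  r4 <- clam_classify(clam_input(c(0, 10), c(0, 10)), coverage_limit = 0)
  expect_identical(r4$category[1], "absent")

  expect_error(clam_classify(clam_input(1, 1, n_a = 0, n_b = 5)), "positive")
  expect_error(clam_classify(clam_input(1, 1), alpha = 0.6), "alpha")
})

test_that("classification agrees with brute-force tail enumeration", {
  grid <- expand.grid(n_a = c(10000, 30000), n_b = c(10000, 7000),
                      k = c(2 / 3, 0.7), alpha = c(0.0025, 0.05))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    for (t in c(1:12, 20, 35, 60)) {
      expect_identical(
        classify_sweep(t, g$n_a, g$n_b, g$k, g$alpha),
        oracle_clam_categories(t, g$n_a, g$n_b, g$k, g$alpha),
        info = sprintf("n_a=%d n_b=%d k=%.3f alpha=%.4f t=%d",
                       g$n_a, g$n_b, g$k, g$alpha, t))
    }
  }
})

test_that("classification is monotone in y_a and symmetric in habitats", {
  for (t in c(5, 17, 40)) {
    cats <- classify_sweep(t, 20000, 15000, 2 / 3, 0.0025)
    # once specialist_a, larger y_a can never become specialist_b
    first_a <- match("specialist_a", cats)
    if (!is.na(first_a))
      expect_true(all(cats[first_a:(t + 1)] == "specialist_a"))
    last_b <- max(which(cats == "specialist_b"), 0)
    if (last_b > 0)
      expect_true(all(cats[1:last_b] == "specialist_b"))
  }

  # habitat swap permutes the specialist labels
  set.seed(61)
  y_a <- rpois(40, 30); y_b <- rpois(40, 30)
  fwd <- clam_classify(clam_input(y_a, y_b, n_a = 5e4, n_b = 3e4),
                       coverage_limit = 0)$category
  rev <- clam_classify(clam_input(y_b, y_a, n_a = 3e4, n_b = 5e4),
                       coverage_limit = 0)$category
  swap <- c(specialist_a = "specialist_b", specialist_b = "specialist_a",
            generalist = "generalist", too_rare = "too_rare",
            absent = "absent")
  expect_identical(unname(swap[fwd]), rev)
})

test_that("coverage adjustment discounts sparse counts by Good-Turing coverage", {
  # habitat A with many singletons has low coverage; a rare count gets
  # multiplied by C_a = 1 - f1_a/N_a and rounded half-up
  y_a <- c(20, rep(1, 10), 169)  # N_a = 199, f1 = 10 -> C_a = 189/199
  y_b <- c(5, rep(2, 10), 174)   # N_b = 199, f1 = 0  -> C_b = 1
  res <- clam_classify(clam_input(y_a, y_b), coverage_limit = 30)
  expect_equal(res$adj_a[1], round_half_up(20 * (1 - 10 / 199)))
  expect_equal(res$adj_b[1], 5)           # C_b = 1
  expect_equal(res$adj_a[12], 169)        # above the coverage limit
  # disabling the limit leaves counts untouched
  res0 <- clam_classify(clam_input(y_a, y_b), coverage_limit = 0)
  expect_equal(res0$adj_a, res0$y_a)
})

test_that("clear-cut cases agree with an independent implementation", {
  skip_if_not_installed("vegan")
  y_a <- c(1000, 10, 500, 1, 3000, 0)
  y_b <- c(10, 1000, 500, 1, 3000, 800)
  comm <- rbind(A = y_a, B = y_b)
  colnames(comm) <- sprintf("sp%d", 1:6)
  ref <- vegan::clamtest(comm, groups = c("A", "B"),
                         coverage.limit = 30, specialization = 2 / 3,
                         npoints = 20, alpha = 0.05 / 20)
  ours <- clam_classify(clam_input(y_a, y_b), threshold = 2 / 3,
                        alpha = 0.05 / 20, coverage_limit = 30)
  map <- c(specialist_a = "Specialist_A", specialist_b = "Specialist_B",
           generalist = "Generalist", too_rare = "Too_rare")
  # large, unambiguous taxa must agree between exact and approximate tests
  big <- c(1, 2, 3, 5)
  expect_identical(unname(map[ours$category[big]]),
                   as.character(ref$Classes[big]))
})

test_that("summaries reproduce printed-percentage arithmetic", {
  expect_equal(pct_half_up(63060, 173769), 36.29)
  expect_equal(format_percent(1322, 173769), "0.76% (1322 out of 173769)")
  expect_equal(pct_half_up(0, 50), 0)

  y_a <- c(900, 3, 400, 0, 2)
  y_b <- c(5, 850, 420, 7, 1)
  res <- clam_classify(clam_input(y_a, y_b), coverage_limit = 0)
  smry <- clam_summary(res)
  expect_equal(sum(smry$taxa$count), 5)
  expect_equal(sum(smry$reads$count), sum(y_a + y_b))
  expect_equal(smry$taxa$pct,
               pct_half_up(smry$taxa$count, sum(smry$taxa$count)))
  expect_output(print(smry), "out of")
})

test_that("planted specialists are recovered from simulated communities", {
  hits <- 0; planted <- 0
  for (r in 1:15) {
    d <- synthetic_design(n_sites = 4, layers = c("upper", "deeper"),
                          contamination_levels = c("0", "30"),
                          n_taxa = 300, specialist_effect = 50,
                          depth_meanlog = log(1e4), seed = 400 + r)
    sim <- simulate_community(d)
    res <- clam_classify(pool_by_habitat(sim$table, sim$metadata, "oiled"))
    truth <- sim$truth$habitat[match(res$taxon_id, sim$truth$taxon_id)]
    spec_c <- truth == "specialist_contaminated"
    spec_u <- truth == "specialist_uncontaminated"
    hits <- hits + sum(res$category[spec_c] == "specialist_a") +
      sum(res$category[spec_u] == "specialist_b")
    planted <- planted + sum(spec_c) + sum(spec_u)
  }
  expect_gte(hits / planted, 0.9)
})
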