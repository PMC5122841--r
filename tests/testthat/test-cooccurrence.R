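test_that("filter_rare keeps taxa at or above the mean-abundance floor", {
  # sample totals 10000 each; taxon means 0.02%, 0.01%, 0.005%
  m <- rbind(major = c(9996, 9997),
             at_2e4 = c(2, 2),
             at_1e4 = c(1, 1),
             never = c(1, 0))
  colnames(m) <- c("s1", "s2")
  # means: at_2e4 = 2e-4, at_1e4 = 1e-4 (exactly the floor), never = 0.5e-4
  tab <- abundance_table(m)
  kept <- filter_rare(tab, 1e-4)
  expect_setequal(rownames(kept), c("major", "at_2e4", "at_1e4"))

  expect_error(filter_rare(tab, 0.9999), "threshold")

  rt <- random_table(50, 6, seed = 91, lambda = 5)
  kept2 <- filter_rare(rt, 0.01)
  brute <- rowMeans(sweep(unclass(rt), 2, colSums(unclass(rt)), "/"))
  expect_setequal(rownames(kept2), names(brute)[brute >= 0.01])
})

test_that("spearman screen reproduces rank statistics and the pass rule", {
  m <- rbind(up = c(1, 2, 3, 4, 5, 6),
             up2 = c(2, 4, 6, 8, 10, 12),
             down = c(6, 5, 4, 3, 2, 1),
             flat = c(7, 7, 7, 7, 7, 7))
  colnames(m) <- sprintf("s%d", 1:6)
  sc <- spearman_screen(abundance_table(m))
  row <- function(a, b) sc[sc$taxon_a == min(a, b) & sc$taxon_b == max(a, b), ]
  expect_equal(row("up", "up2")$rho, 1)
  expect_equal(row("up", "up2")$p_value, 0)
  expect_true(row("up", "up2")$pass)
  expect_equal(row("up", "down")$rho, -1)
  expect_false(row("up", "down")$pass)
  expect_true(row("up", "flat")$zero_variance)
  expect_false(row("up", "flat")$pass)

  # tied vector against the explicit average-rank formula
  x <- c(1, 2, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 6, 5)
  m2 <- rbind(a = x, b = y)
  colnames(m2) <- sprintf("s%d", 1:6)
  sc2 <- spearman_screen(abundance_table(m2))
  rho_manual <- cor(rank(x), rank(y))
  expect_equal(sc2$rho, rho_manual)
  tt <- rho_manual * sqrt(4 / (1 - rho_manual^2))
  expect_equal(sc2$p_value, 2 * pt(-abs(tt), 4))

  expect_error(spearman_screen(random_table(5, 3, seed = 1)), "4 samples")
})

test_that("spearman p-values match cor.test's t approximation", {
  set.seed(71)
  rt <- random_table(8, 10, seed = 71)
  sc <- spearman_screen(rt)
  m <- unclass(rt)
  for (i in sample(nrow(sc), 5)) {
    ct <- suppressWarnings(cor.test(m[sc$taxon_a[i], ], m[sc$taxon_b[i], ],
                                    method = "spearman", exact = FALSE))
    expect_equal(sc$rho[i], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(sc$p_value[i], ct$p.value, tolerance = 1e-12)
  }
})

test_that("affiliation projection counts shared samples", {
  m <- rbind(A = c(1, 5, 2, 0, 0),
             B = c(0, 3, 1, 0, 7),
             C = c(0, 0, 0, 0, 0))
  colnames(m) <- sprintf("s%d", 1:5)
  net <- project_affiliation(abundance_table(m))
  expect_setequal(net$nodes, c("A", "B", "C"))
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$e_weight, 2)  # shared samples s2, s3
  summ <- node_summaries(net)
  expect_equal(summ$connections[summ$taxon == "C"], 0)

  # brute-force set-intersection oracle on random presence patterns
  for (r in 1:10) {
    rt <- random_table(12, 9, seed = 200 + r, lambda = 1)
    net_r <- project_affiliation(rt)
    pres <- unclass(rt) > 0
    for (i in seq_len(nrow(net_r$edges))) {
      e <- net_r$edges[i, ]
      expect_equal(e$e_weight,
                   sum(pres[e$taxon_a, ] & pres[e$taxon_b, ]))
    }
    expect_true(all(net_r$edges$e_weight <= 9))
  }
})

test_that("projection agrees with igraph bipartite projection", {
  rt <- random_table(15, 8, seed = 55, lambda = 2)
  net <- project_affiliation(rt)
  pres <- unclass(rt) > 0
  inc <- igraph::graph_from_biadjacency_matrix(pres)
  proj <- igraph::bipartite_projection(inc, multiplicity = TRUE)$proj1
  ref <- igraph::as_data_frame(proj)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  ours <- setNames(net$edges$e_weight,
                   key(net$edges$taxon_a, net$edges$taxon_b))
  theirs <- setNames(ref$weight, key(ref$from, ref$to))
  expect_setequal(names(ours), names(theirs))
  expect_equal(unname(ours[names(theirs)]), unname(theirs))
})

test_that("screened networks are subgraphs of the unscreened projection", {
  d <- synthetic_design(n_sites = 4, layers = c("upper", "deeper"),
                        contamination_levels = c("0", "30"),
                        n_taxa = 60, specialist_effect = 1,
                        fraction_specialist_contaminated = 0,
                        fraction_specialist_uncontaminated = 0,
                        fraction_generalist = 0.9, fraction_rare = 0.1,
                        n_guilds = 2, guild_size = 5,
                        depth_meanlog = log(3000), seed = 77)
  sim <- simulate_community(d)
  kept <- filter_rare(sim$table)
  sc <- spearman_screen(kept)
  net_all <- project_affiliation(kept)
  net_scr <- project_affiliation(kept, sc)
  key <- function(e) paste(e$taxon_a, e$taxon_b)
  expect_true(all(key(net_scr$edges) %in% key(net_all$edges)))
  merged <- match(key(net_scr$edges), key(net_all$edges))
  expect_equal(net_scr$edges$e_weight, net_all$edges$e_weight[merged])
  expect_true(all(!is.na(net_scr$edges$rho)))

  # removing a sample never increases any e-weight
  sub_tab <- abundance_table(unclass(sim$table)[, -3])
  net_sub <- project_affiliation(filter_rare(sub_tab))
  common <- intersect(key(net_sub$edges), key(net_all$edges))
  a <- net_sub$edges$e_weight[match(common, key(net_sub$edges))]
  b <- net_all$edges$e_weight[match(common, key(net_all$edges))]
  expect_true(all(a <= b))
})

test_that("subnetwork induces exact subgraphs", {
  rt <- random_table(10, 6, seed = 31, lambda = 3)
  net <- project_affiliation(rt)
  all_sub <- subnetwork(net, net$nodes)
  expect_equal(all_sub$edges, net$edges)

  two <- subnetwork(net, net$nodes[1:2])
  expect_length(two$nodes, 2)
  expect_error(subnetwork(net, c("t001", "ghost")), "ghost")

  some <- subnetwork(net, net$nodes[c(1, 3, 5, 7)])
  key <- function(e) paste(e$taxon_a, e$taxon_b)
  idx <- match(key(some$edges), key(net$edges))
  expect_false(anyNA(idx))
  expect_equal(some$edges$e_weight, net$edges$e_weight[idx])
})

test_that("upper-half view applies the strict above-median rule", {
  mk <- function(w) {
    nodes <- sprintf("n%d", seq_len(length(w) + 1))
    cooc_network(nodes,
                 data.frame(taxon_a = nodes[seq_along(w)],
                            taxon_b = nodes[seq_along(w) + 1],
                            e_weight = w, stringsAsFactors = FALSE),
                 n_samples = 16)
  }
  # all equal weights: nothing is strictly above the median
  expect_equal(nrow(upper_half_view(mk(c(4, 4, 4)))$edges), 0)
  # odd count {1,2,3}: median 2, only the 3 survives
  uh <- upper_half_view(mk(c(1, 2, 3)))
  expect_equal(uh$edges$e_weight, 3)
  # even count {1,1,5,5}: midpoint median 3, both 5s survive
  uh2 <- upper_half_view(mk(c(1, 1, 5, 5)))
  expect_equal(uh2$edges$e_weight, c(5, 5))
  expect_length(uh2$nodes, 5)  # nodes retained even when isolated
  expect_error(upper_half_view(mk(numeric(0))), "no edges")
})

test_that("node summaries list tied strongest partners Table-style", {
  nodes <- c("center", "leafA", "leafB", "leafC")
  net <- cooc_network(nodes, data.frame(
    taxon_a = c("center", "center", "center"),
    taxon_b = c("leafA", "leafB", "leafC"),
    e_weight = c(5, 5, 2), stringsAsFactors = FALSE), n_samples = 8)
  summ <- node_summaries(net)
  ctr <- summ[summ$taxon == "center", ]
  expect_equal(ctr$connections, 3)
  expect_equal(ctr$strongest_partners, "leafA, leafB")
  expect_equal(ctr$strongest_e_weight, 5)
  # sorted by strongest e-weight, then connections, then name
  expect_equal(summ$taxon[1], "center")

  # complete graph on 15 nodes: every node has 14 connections
  n <- 15
  nodes15 <- sprintf("g%02d", 1:n)
  pairs <- t(combn(nodes15, 2))
  set.seed(8)
  kn <- cooc_network(nodes15, data.frame(
    taxon_a = pairs[, 1], taxon_b = pairs[, 2],
    e_weight = sample(5:16, nrow(pairs), replace = TRUE),
    stringsAsFactors = FALSE), n_samples = 16)
  s15 <- node_summaries(kn)
  expect_equal(s15$connections, rep(14L, 15))
})

test_that("chord matrices carry sector-width semantics", {
  net <- cooc_network(c("A", "B"), data.frame(
    taxon_a = "A", taxon_b = "B", e_weight = 7, stringsAsFactors = FALSE),
    n_samples = 12)
  cm <- chord_matrix(net)
  expect_equal(unname(cm), matrix(c(0, 7, 7, 0), 2))
  expect_equal(unname(rowSums(cm)), c(7, 7))

  rt <- random_table(10, 7, seed = 87, lambda = 2)
  netr <- project_affiliation(rt)
  cmr <- chord_matrix(netr)
  expect_equal(cmr, t(cmr))
  expect_equal(unname(diag(cmr)), rep(0, 10))
  for (v in netr$nodes) {
    inc <- netr$edges[netr$edges$taxon_a == v | netr$edges$taxon_b == v, ]
    expect_equal(sum(cmr[v, ]), sum(inc$e_weight))
  }
  # the upper-half matrix is entrywise dominated by its parent
  if (nrow(netr$edges) > 0) {
    cm_uh <- chord_matrix(upper_half_view(netr))
    expect_true(all(cm_uh <= cmr))
  }
})

test_that("networks round-trip through edge-list TSV and GraphML", {
  rt <- random_table(8, 6, seed = 13, lambda = 2)
  sc <- spearman_screen(rt, rho_min = -1, p_max = 1)
  net <- project_affiliation(rt, sc)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, tsv, "edge_list_tsv")
  back <- read_network(tsv, n_samples = net$n_samples)
  expect_equal(back$edges$e_weight, net$edges$e_weight)
  expect_equal(back$edges$rho, net$edges$rho, tolerance = 1e-12)
  expect_true(all(back$edges$taxon_a < back$edges$taxon_b))

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gsize(g), nrow(net$edges))
  expect_setequal(igraph::V(g)$name, net$nodes)
  expect_equal(sort(igraph::E(g)$weight), sort(net$edges$e_weight))

  # empty graph: header-only edge list
  empty <- cooc_network("solo", data.frame(taxon_a = character(0),
                                           taxon_b = character(0),
                                           e_weight = numeric(0)),
                        n_samples = 4)
  tsv2 <- withr::local_tempfile(fileext = ".tsv")
  write_network(empty, tsv2)
  expect_length(readLines(tsv2), 1)
})

test_that("guild edges pass the screen, unrelated edges mostly fail", {
  win <- c(); btw <- c()
  for (r in 1:20) {
    d <- synthetic_design(n_sites = 4, layers = c("upper", "deeper"),
                          contamination_levels = c("0", "30"),
                          n_taxa = 150, specialist_effect = 1,
                          fraction_specialist_contaminated = 0,
                          fraction_specialist_uncontaminated = 0,
                          fraction_generalist = 0.9, fraction_rare = 0.1,
                          n_guilds = 2, guild_size = 5,
                          guild_correlation = 0.9,
                          depth_meanlog = log(1e4), seed = 900 + r)
    sim <- simulate_community(d)
    sc <- spearman_screen(sim$table)
    g <- sim$truth$guild[match(sc$taxon_a, sim$truth$taxon_id)]
    h <- sim$truth$guild[match(sc$taxon_b, sim$truth$taxon_id)]
    win <- c(win, sc$pass[!is.na(g) & !is.na(h) & g == h])
    btw <- c(btw, sc$pass[!is.na(g) & !is.na(h) & g != h])
  }
  expect_gte(mean(win), 0.8)
  expect_lte(mean(btw), 0.05)
})
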