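#' Describe a synthetic community design
#'
#' Declares the factorial layout (sites x layers x contamination loads x
#' replicates) and the statistical structure of a simulated genus-level
#' community: habitat specialists whose expected relative abundance is
#' boosted by `specialist_effect` in their preferred habitat (contaminated
#' or uncontaminated), broadly distributed generalists, rare taxa kept
#' below the 0.01% relative-abundance filter, and co-occurring guilds tied
#' together by a shared per-sample log-normal latent factor.
#'
#' @param n_sites number of sampling sites (up to 4 get the site codes
#'   WN, WL, TY, JQ; more are numbered).
#' @param layers subset of `c("upper", "deeper")`.
#' @param contamination_levels subset of `c("0", "30", "50")` (% v/w oil).
#' @param replicates microcosm replicates per design cell.
#' @param n_taxa number of genus-level taxa.
#' @param fraction_specialist_contaminated,fraction_specialist_uncontaminated,fraction_generalist,fraction_rare
#'   proportions of taxa in each planted habitat class; must sum to 1.
#' @param specialist_effect fold-change (>= 1) of a specialist's expected
#'   weight in its preferred habitat relative to the other habitat.
#' @param n_guilds,guild_size number and size of co-occurring guilds;
#'   members are drawn without replacement from the generalist taxa.
#' @param guild_correlation latent-factor loading in [0, 1); guild
#'   members share one per-sample log-normal factor whose log-sd is
#'   `guild_sdlog * guild_correlation`, so 0 disables guild structure and
#'   values near 1 give tightly co-occurring members.
#' @param guild_sdlog log-sd scale of the shared guild fluctuation.
#' @param depth_meanlog,depth_sdlog log-normal sequencing-depth
#'   distribution; defaults emulate one 454 run of roughly 6300 reads per
#'   sample varying by about 25%.
#' @param overdispersion Dirichlet concentration scalar; per-sample
#'   compositions are Dirichlet(overdispersion x expected composition), so
#'   larger values mean counts closer to multinomial.
#' @param rare_target expected relative abundance ceiling for rare taxa
#'   (default half of the 1e-4 network filter).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return a `synthetic_design` list.
#' @export
synthetic_design <- function(n_sites = 4,
                             layers = c("upper", "deeper"),
                             contamination_levels = c("0", "30", "50"),
                             replicates = 1,
                             n_taxa = 300,
                             fraction_specialist_contaminated = 0.25,
                             fraction_specialist_uncontaminated = 0.25,
                             fraction_generalist = 0.40,
                             fraction_rare = 0.10,
                             specialist_effect = 10,
                             n_guilds = 2,
                             guild_size = 5,
                             guild_correlation = 0.9,
                             guild_sdlog = 1.5,
                             depth_meanlog = log(6300),
                             depth_sdlog = 0.25,
                             overdispersion = 5000,
                             rare_target = 5e-5,
                             seed = 1) {
  fr <- c(fraction_specialist_contaminated, fraction_specialist_uncontaminated,
          fraction_generalist, fraction_rare)
  if (abs(sum(fr) - 1) > 1e-12)
    stop("habitat-class fractions must sum to 1", call. = FALSE)
  if (specialist_effect < 1) stop("specialist_effect must be >= 1", call. = FALSE)
  if (guild_correlation < 0 || guild_correlation >= 1)
    stop("guild_correlation must be in [0, 1)", call. = FALSE)
  layers <- match.arg(layers, c("upper", "deeper"), several.ok = TRUE)
  contamination_levels <- match.arg(contamination_levels, c("0", "30", "50"),
                                    several.ok = TRUE)
  design <- list(
    n_sites = as.integer(n_sites), layers = layers,
    contamination_levels = contamination_levels,
    replicates = as.integer(replicates), n_taxa = as.integer(n_taxa),
    fractions = c(specialist_contaminated = fr[1],
                  specialist_uncontaminated = fr[2],
                  generalist = fr[3], rare = fr[4]),
    specialist_effect = specialist_effect,
    n_guilds = as.integer(n_guilds), guild_size = as.integer(guild_size),
    guild_correlation = guild_correlation, guild_sdlog = guild_sdlog,
    depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
    overdispersion = overdispersion, rare_target = rare_target,
    seed = as.integer(seed))
  class(design) <- "synthetic_design"
  design
}

# Run code with a temporary RNG state seeded from `seed`.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

sample_frame <- function(design) {
  site_codes <- c("WN", "WL", "TY", "JQ")
  sites <- if (design$n_sites <= 4) site_codes[seq_len(design$n_sites)]
           else sprintf("S%02d", seq_len(design$n_sites))
  grid <- expand.grid(rep = seq_len(design$replicates),
                      contamination = design$contamination_levels,
                      layer = design$layers, site = sites,
                      stringsAsFactors = FALSE)
  layer_code <- c(upper = "a", deeper = "d")[grid$layer]
  contam_code <- c("0" = "0", "30" = "3", "50" = "5")[grid$contamination]
  id <- paste0(grid$site, layer_code, contam_code)
  if (design$replicates > 1) id <- paste0(id, "_r", grid$rep)
  data.frame(sample_id = id, site = grid$site, layer = grid$layer,
             contamination = grid$contamination, stringsAsFactors = FALSE)
}

#' Simulate a community with planted structure
#'
#' Draws genus baseline weights log-normally (one draw per taxon), boosts
#' specialists in their preferred habitat by `specialist_effect`, applies a
#' shared log-normal latent factor to guild members, then draws each
#' sample's composition from a Dirichlet centred on the expected weights
#' and its counts from a multinomial at a log-normal sequencing depth.
#' Rare taxa are rescaled so their expected relative abundance stays below
#' `rare_target` in every sample.
#'
#' @param design a [synthetic_design()].
#' @return list with `table` (an [abundance_table()]), `metadata`
#'   (a [sample_metadata()]) and `truth` (data.frame of planted per-taxon
#'   habitat labels and guild ids).
#' @export
simulate_community <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  meta <- sample_frame(design)
  n_s <- nrow(meta)
  n_t <- design$n_taxa
  contaminated <- meta$contamination != "0"

  n_class <- class_counts(n_t, design$fractions)
  labels <- rep(names(n_class), n_class)
  if ((n_class[["specialist_contaminated"]] > 0 &&
       sum(contaminated) < 2) ||
      (n_class[["specialist_uncontaminated"]] > 0 &&
       sum(!contaminated) < 2))
    stop("specialists planted but a habitat has fewer than 2 samples",
         call. = FALSE)

  taxon_ids <- sprintf("genus_%03d", seq_len(n_t))
  guild <- rep(NA_integer_, n_t)
  gen_idx <- which(labels == "generalist")
  need <- design$n_guilds * design$guild_size
  if (need > 0) {
    if (need > length(gen_idx))
      stop("guilds need ", need, " generalist taxa but only ",
           length(gen_idx), " available", call. = FALSE)
    members <- local_seed(derive_seed(design$seed, "guild_pick"),
                          sample(gen_idx, need))
    guild[members] <- rep(seq_len(design$n_guilds), each = design$guild_size)
  }

  base <- local_seed(derive_seed(design$seed, "base"),
                     stats::rlnorm(n_t, meanlog = 0, sdlog = 1))
  rare <- labels == "rare"
  if (any(rare)) {
    # deterministic ceiling: max expected share of a rare taxon < rare_target
    base[rare] <- base[rare] *
      design$rare_target * sum(base[!rare]) / max(base[rare])
  }

  # taxa x samples expected weights
  w <- matrix(base, n_t, n_s)
  eff <- design$specialist_effect
  w[labels == "specialist_contaminated", contaminated] <-
    w[labels == "specialist_contaminated", contaminated] * eff
  w[labels == "specialist_uncontaminated", !contaminated] <-
    w[labels == "specialist_uncontaminated", !contaminated] * eff

  if (design$n_guilds > 0 && any(!is.na(guild))) {
    # one latent factor per guild and sample, shared by all members and
    # scaled by the loading; members decorrelate only through sampling
    # noise, so the loading controls how tight the planted guild is
    lam <- design$guild_correlation
    z <- local_seed(derive_seed(design$seed, "guild_factor"),
                    matrix(stats::rnorm(design$n_guilds * n_s),
                           design$n_guilds, n_s))
    for (i in which(!is.na(guild))) {
      logf <- design$guild_sdlog * lam * z[guild[i], ]
      w[i, ] <- w[i, ] * exp(logf)
    }
  }

  depth <- local_seed(derive_seed(design$seed, "depth"),
                      pmax(1L, as.integer(round(stats::rlnorm(
                        n_s, design$depth_meanlog, design$depth_sdlog)))))

  counts <- local_seed(derive_seed(design$seed, "counts"), {
    out <- matrix(0L, n_t, n_s)
    for (s in seq_len(n_s)) {
      alpha <- design$overdispersion * w[, s] / sum(w[, s])
      g <- stats::rgamma(n_t, shape = alpha, rate = 1)
      if (sum(g) <= 0) g[] <- alpha  # degenerate draw guard
      p <- g / sum(g)
      out[, s] <- stats::rmultinom(1, size = depth[s], prob = p)[, 1]
    }
    out
  })
  dimnames(counts) <- list(taxon_ids, meta$sample_id)

  truth <- data.frame(taxon_id = taxon_ids, habitat = labels,
                      guild = guild, stringsAsFactors = FALSE)
  list(table = abundance_table(counts),
       metadata = sample_metadata(meta),
       truth = truth)
}

class_counts <- function(n_taxa, fractions) {
  n <- floor(fractions * n_taxa)
  rem <- n_taxa - sum(n)
  # distribute the remainder by largest fractional part, ties by order
  if (rem > 0) {
    extra <- order(fractions * n_taxa - n, decreasing = TRUE)[seq_len(rem)]
    n[extra] <- n[extra] + 1
  }
  stats::setNames(as.integer(n), c("specialist_contaminated",
                                   "specialist_uncontaminated",
                                   "generalist", "rare"))
}

#' Built-in synthetic design presets
#'
#' `"paper_like"` mirrors a compiled permafrost microcosm design: 4 sites
#' x upper/deeper layers x {0, 30, 50}% v/w crude-oil loads, one pooled
#' sample per cell (24 samples). `"tiny"` is a 4-taxon, 4-sample smoke
#' fixture.
#'
#' @return named list of [synthetic_design()] objects.
#' @export
synthetic_presets <- function() {
  list(
    paper_like = synthetic_design(seed = 20161125),
    tiny = synthetic_design(n_sites = 2, layers = "upper",
                            contamination_levels = c("0", "30"),
                            n_taxa = 4,
                            fraction_specialist_contaminated = 0,
                            fraction_specialist_uncontaminated = 0,
                            fraction_generalist = 1, fraction_rare = 0,
                            n_guilds = 0, guild_size = 0,
                            depth_meanlog = log(200), seed = 42))
}

#' Write a synthetic fixture to disk
#'
#' Emits `table.tsv` (abundance matrix), `metadata.tsv` and `truth.tsv`
#' for a named preset. Deterministic: re-running a preset reproduces the
#' files byte for byte.
#'
#' @param preset preset name, see [synthetic_presets()].
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
emit_fixture <- function(preset, dir) {
  presets <- synthetic_presets()
  if (!preset %in% names(presets))
    stop("unknown preset '", preset, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  sim <- simulate_community(presets[[preset]])
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("table.tsv", "metadata.tsv", "truth.tsv"))
  write_abundance_table(sim$table, paths[1])
  utils::write.table(as.data.frame(sim$metadata)[
    c("sample_id", "site", "layer", "contamination")],
    paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
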