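Package: permanet
Title: Habitat Specialists, Diversity and Co-Occurrence Networks for
    Taxon Abundance Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream community analysis for 16S-derived taxon-by-sample
    count tables: alpha-diversity estimators (Shannon, Chao1, ACE) and
    exact hypergeometric rarefaction curves; rank-level relative-abundance
    profiling with top-k tables and hierarchical heatmap structure;
    Bray-Curtis dissimilarity, principal coordinates analysis and
    one-factor permutational multivariate ANOVA; multinomial habitat
    specialist/generalist (CLAM) classification with exact binomial
    boundary tests and Good-Turing coverage adjustment; and
    Spearman-screened co-occurrence network construction by bipartite
    affiliation-network projection, with specialist subnetworks,
    above-median-edge views, keystone node summaries and chord-diagram
    matrices. Includes a Dirichlet-multinomial synthetic community
    generator with planted specialists, generalists, rare taxa and
    co-occurring guilds for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    igraph,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
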