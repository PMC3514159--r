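toy_star <- function() {
  ppi_network(cbind(rep("c", 4), paste0("l", 1:4)))
}

test_that("second-degree expansion excludes seeds, bait and self-loops", {
  expect_identical(second_degree(toy_star(), "c"), paste0("l", 1:4))
  path <- ppi_network(rbind(c("a", "b"), c("b", "c")))
  expect_identical(second_degree(path, c("a", "c")), "b")
  expect_identical(second_degree(path, "b", bait = "c"), "a")

  only_loop <- ppi_network(rbind(c("a", "a"), c("x", "y")))
  expect_warning(out <- second_degree(only_loop, "a"), "empty")
  expect_identical(out, character(0))
  expect_error(second_degree(path, c("zz", "qq")), "none of the")
  expect_warning(second_degree(path, c("a", "zz")), "absent")
})

test_that("observed pathway counts are distinct-protein intersections", {
  col <- gene_set_collection("s", list(
    P1 = list(name = "", members = c("x", "y", "w")),
    P2 = list(name = "", members = c("q", "r")),
    P3 = list(name = "", members = c("x", "y"))
  ))
  obs <- observed_pathway_counts(c("x", "y", "z"), col)
  expect_equal(unname(obs), c(2L, 0L, 2L))
  expect_equal(unname(observed_pathway_counts(character(0), col)),
               c(0L, 0L, 0L))
})

test_that("null seed sets are reproducible, sized, and uniform", {
  net <- ppi_network(cbind(paste0("n", 1:9), paste0("n", c(2:9, 1))),
                     nodes = paste0("n", 1:10))
  cfg <- permutation_config(n_trials = 3L, rng_seed = 42L)
  s1 <- sample_null_seed_sets(net, 2L, cfg)
  s2 <- sample_null_seed_sets(net, 2L, cfg)
  expect_identical(unclass(s1)[, ], unclass(s2)[, ])
  expect_equal(dim(s1), c(2L, 3L))
  expect_equal(length(as.list(s1)[[1]]), 2L)

  full <- sample_null_seed_sets(net, 10L,
                                permutation_config(n_trials = 2L,
                                                   rng_seed = 1L))
  expect_true(all(apply(full, 2, sort) == 1:10))
  expect_error(sample_null_seed_sets(net, 11L, cfg), "exceeds")

  # inclusion frequency: each node enters a k=2-of-10 draw w.p. 0.2
  cfg2 <- permutation_config(n_trials = 10000L, rng_seed = 7L)
  draws <- sample_null_seed_sets(net, 2L, cfg2)
  freq <- tabulate(as.integer(draws), nbins = 10L) / 10000
  expect_true(all(abs(freq - 0.2) <= 3 * sqrt(0.2 * 0.8 / 10000)))
})

test_that("degree-matched sampling respects the seeds' degree bins", {
  # hub h (degree 6) plus a 6-cycle of degree-2 nodes
  edges <- rbind(cbind("h", paste0("v", 1:6)),
                 cbind(paste0("v", 1:6), paste0("v", c(2:6, 1))))
  net <- ppi_network(edges)
  cfg <- permutation_config(n_trials = 50L, rng_seed = 5L,
                            sampling = "degree_matched")
  draws <- sample_null_seed_sets(net, 2L, cfg, seeds = c("h", "v1"))
  deg <- lengths(seedenrich:::network_adjacency(net))
  # h has degree 6 (bin log2 = 2); every cycle node has degree 3 (bin 1)
  for (j in seq_len(ncol(draws))) {
    expect_equal(sort(deg[draws[, j]]), c(3L, 6L))
  }
})

test_that("empirical FDR is an exceedance proportion with optional smoothing", {
  expect_equal(empirical_fdr(0, c(0L, 5L, 2L)), 1.0)
  expect_equal(empirical_fdr(2, c(0L, 0L, 1L, 2L)), 0.25)
  expect_equal(empirical_fdr(99, c(0L, 1L)), 0.0)
  expect_equal(empirical_fdr(99, c(0L, 1L), smoothing = "add_one"), 1 / 3)
  # monotone non-increasing in obs for a fixed null sample
  nulls <- c(0L, 1L, 1L, 2L, 3L, 5L)
  fdrs <- vapply(0:6, empirical_fdr, numeric(1), null_counts = nulls)
  expect_true(all(diff(fdrs) <= 0) && all(fdrs >= 0 & fdrs <= 1))
})

test_that("Bonferroni correction reproduces published corrected FDRs", {
  expect_equal(bonferroni_correct(5.00e-5, 628L), 3.14e-2, tolerance = 1e-9)
  expect_equal(bonferroni_correct(1.00e-4, 150L), 1.50e-2, tolerance = 1e-9)
  expect_equal(bonferroni_correct(0.2, 10L), 1.0)
})

test_that("the batch kernel matches per-trial R expansion exactly", {
  cfg_net <- synthetic_config(n_genes = 25L,
                              network_model = list(model = "erdos_renyi",
                                                   p = 0.2),
                              n_sets = 6L, set_size_range = c(3L, 8L),
                              n_seeds = 3L, rng_seed = 21L)
  net <- gen_network(cfg_net)
  col <- gen_gene_sets(cfg_net, synthetic_universe(25L))
  cfg <- permutation_config(n_trials = 40L, rng_seed = 9L)
  trials <- sample_null_seed_sets(net, 3L, cfg)
  adj <- seedenrich:::network_adjacency(net)
  members_idx <- lapply(col$sets, function(s)
    match(intersect(s$members, net$nodes), net$nodes))
  bait <- net$nodes[1]
  counts <- seedenrich:::cpp_null_pathway_counts(
    adj, members_idx, matrix(as.integer(trials), nrow = 3L),
    1L, length(net$nodes))
  for (j in seq_len(ncol(trials))) {
    seeds_j <- net$nodes[trials[, j]]
    ind <- suppressWarnings(second_degree(net, seeds_j, bait = bait))
    expect_equal(counts[, j], unname(observed_pathway_counts(ind, col)))
  }
})

test_that("empirical FDR matches exhaustive enumeration on a small network", {
  # 6-node toy network, k = 2: the 15-trial null is the full seed-pair space
  edges <- rbind(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "e"),
                 c("e", "f"), c("b", "e"))
  nodes <- letters[1:6]
  pathway <- c("c", "d", "f")
  seeds <- c("a", "e")
  ind <- second_degree(ppi_network(edges, nodes), seeds)
  obs <- length(intersect(ind, pathway))
  oracle <- exhaustive_exceedance(edges, nodes, 2L, pathway, obs)
  null_counts <- vapply(utils::combn(nodes, 2L, simplify = FALSE),
                        function(ss) {
    inds <- suppressWarnings(second_degree(ppi_network(edges, nodes), ss))
    length(intersect(inds, pathway))
  }, integer(1))
  expect_equal(empirical_fdr(obs, null_counts), oracle$exceedance)

  # Monte-Carlo at 50,000 trials agrees within 3 binomial standard errors
  net8 <- ppi_network(rbind(edges, c("f", "g"), c("g", "h"), c("h", "a")),
                      letters[1:8])
  oracle8 <- exhaustive_exceedance(net8$edges, net8$nodes, 2L, pathway,
                                   obs = 2L)
  col <- gene_set_collection("s", list(P = list(name = "", members = pathway)))
  cfg <- permutation_config(n_trials = 50000L, rng_seed = 13L)
  trials <- sample_null_seed_sets(net8, 2L, cfg)
  counts <- seedenrich:::cpp_null_pathway_counts(
    seedenrich:::network_adjacency(net8),
    list(match(intersect(pathway, net8$nodes), net8$nodes)),
    matrix(as.integer(trials), nrow = 2L), 0L, length(net8$nodes))
  mc <- mean(counts[1, ] >= 2L)
  f <- oracle8$exceedance
  expect_lte(abs(mc - f), 3 * sqrt(f * (1 - f) / 50000))
})

test_that("indirect enrichment applies the significance rule and is deterministic", {
  cfg_net <- synthetic_config(n_genes = 60L,
                              network_model = list(model = "erdos_renyi",
                                                   p = 0.08),
                              n_sets = 8L, set_size_range = c(4L, 10L),
                              n_seeds = 6L, rng_seed = 31L)
  net <- gen_network(cfg_net)
  uni <- synthetic_universe(60L)
  col <- gen_gene_sets(cfg_net, uni)
  seeds <- plant_direct(cfg_net, uni, col$sets[[1]]$members)
  cfg <- permutation_config(n_trials = 200L, rng_seed = 3L)
  r1 <- run_indirect_enrichment(net, seeds, bait = NULL, col, cfg)
  r2 <- run_indirect_enrichment(net, seeds, bait = NULL, col, cfg)
  expect_identical(r1, r2)
  expect_true(all(r1$empirical_fdr >= 0 & r1$empirical_fdr <= 1))
  expect_true(all(r1$corrected_fdr >= r1$empirical_fdr - 1e-15))
  expect_equal(r1$significant,
               r1$corrected_fdr < cfg$alpha & r1$obs >= cfg$min_obs)
  expect_true(all(diff(r1$empirical_fdr) >= 0))  # sorted by empirical FDR
  expect_equal(unname(attr(r1, "m_per_source")["synthetic"]), nrow(r1))
  # a pathway with obs below min_obs is never significant, whatever its FDR
  expect_false(any(r1$significant[r1$obs < cfg$min_obs]))
})

test_that("per-source Bonferroni uses each collection's own test count", {
  nodes <- paste0("n", 1:20)
  net <- ppi_network(cbind(nodes[1:19], nodes[2:20]), nodes)
  colA <- gene_set_collection("A", list(
    A1 = list(name = "", members = nodes[3:6]),
    A2 = list(name = "", members = nodes[8:11])
  ))
  colB <- gene_set_collection("B", list(
    B1 = list(name = "", members = nodes[12:15])
  ))
  cfg <- permutation_config(n_trials = 100L, rng_seed = 2L)
  res <- run_indirect_enrichment(net, nodes[c(4, 9)], bait = NULL,
                                 list(colA, colB), cfg)
  m <- attr(res, "m_per_source")
  expect_equal(unname(m[c("A", "B")]), c(2L, 1L))
  for (i in seq_len(nrow(res))) {
    expect_equal(res$corrected_fdr[i],
                 min(1, res$empirical_fdr[i] * m[[res$source[i]]]))
  }
})
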