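test_that("network generation is deterministic and honors the model", {
  small <- function(n, p, seed) {
    synthetic_config(n_genes = n,
                     network_model = list(model = "erdos_renyi", p = p),
                     n_sets = 4L, set_size_range = c(3L, 6L),
                     n_seeds = 5L, rng_seed = seed)
  }
  cfg0 <- small(50L, 0, 1L)
  expect_equal(nrow(gen_network(cfg0)$edges), 0L)
  expect_equal(length(gen_network(cfg0)$nodes), 50L)  # isolated nodes kept

  cfg1 <- small(80L, 0.05, 4L)
  expect_identical(gen_network(cfg1)$edges, gen_network(cfg1)$edges)
  cfg2 <- small(80L, 0.05, 5L)
  expect_false(identical(gen_network(cfg1)$edges, gen_network(cfg2)$edges))
})

test_that("configuration-model graphs realize an even power-law degree sum", {
  cfg <- synthetic_config(n_genes = 120L,
                          network_model = list(model = "configuration",
                                               gamma = 2.2, min_degree = 1L,
                                               max_degree = 12L),
                          rng_seed = 8L)
  net <- gen_network(cfg)
  deg <- lengths(seedenrich:::network_adjacency(net))
  expect_equal(nrow(net$edges), sum(deg) / 2)  # handshake lemma, simple graph
  expect_true(max(deg) <= 13L)  # at most one degree bumped to even the sum
})

test_that("gene-set generation respects sizes, membership and overlap", {
  uni <- synthetic_universe(100L)
  cfg <- synthetic_config(n_genes = 100L, n_sets = 30L,
                          set_size_range = c(5L, 12L), rng_seed = 6L)
  col <- gen_gene_sets(cfg, uni)
  expect_equal(length(col$sets), 30L)
  sizes <- vapply(col$sets, function(s) length(s$members), integer(1))
  expect_true(all(sizes >= 5L & sizes <= 12L))
  expect_true(all(unlist(lapply(col$sets, `[[`, "members")) %in% uni))
  # overlap is allowed: 30 sets of >= 5 from 100 genes must collide
  expect_gt(length(unlist(lapply(col$sets, `[[`, "members"))),
            length(unique(unlist(lapply(col$sets, `[[`, "members")))))
})

test_that("planted direct seeds meet the quota without duplicates", {
  uni <- synthetic_universe(200L)
  term <- uni[1:40]
  cfg1 <- synthetic_config(n_genes = 200L, n_seeds = 20L, direct_q = 1,
                           rng_seed = 2L)
  s1 <- plant_direct(cfg1, uni, term)
  expect_true(all(s1 %in% term))
  expect_equal(length(unique(s1)), 20L)

  cfg5 <- synthetic_config(n_genes = 200L, n_seeds = 20L, direct_q = 0.5,
                           rng_seed = 2L)
  s5 <- plant_direct(cfg5, uni, term)
  expect_equal(sum(s5 %in% term), 10L)

  cfg_bad <- synthetic_config(n_genes = 200L, n_seeds = 20L, direct_q = 1,
                              rng_seed = 2L)
  expect_error(plant_direct(cfg_bad, uni, uni[1:5]), "infeasible quota")
})

test_that("planting indirect links only adds seed-to-pathway edges", {
  cfg <- synthetic_config(n_genes = 60L,
                          network_model = list(model = "erdos_renyi",
                                               p = 0.05),
                          indirect_k_links = 2L, rng_seed = 12L)
  net <- gen_network(cfg)
  uni <- synthetic_universe(60L)
  pathway <- uni[31:45]
  seeds <- uni[1:5]
  planted <- plant_indirect(cfg, net, pathway, seeds)
  expect_identical(planted$nodes, net$nodes)
  old_keys <- paste(net$edges[, 1], net$edges[, 2])
  new_keys <- paste(planted$edges[, 1], planted$edges[, 2])
  expect_true(all(old_keys %in% new_keys))  # never deletes an edge
  added <- planted$edges[!(new_keys %in% old_keys), , drop = FALSE]
  expect_true(all(apply(added, 1L, function(e) {
    (e[1] %in% seeds & e[2] %in% pathway) |
      (e[2] %in% seeds & e[1] %in% pathway)
  })))
  # per seed: exactly k new neighbors inside the pathway (none pre-linked here)
  expect_equal(nrow(added), 10L)

  cfg0 <- synthetic_config(n_genes = 60L, indirect_k_links = 0L, rng_seed = 1L)
  expect_identical(plant_indirect(cfg0, net, pathway, seeds), net)
  cfg_bad <- synthetic_config(n_genes = 60L, indirect_k_links = 20L,
                              rng_seed = 1L)
  expect_error(plant_indirect(cfg_bad, net, uni[1:10], seeds), "exceeds")
})

test_that("generator calls consume independent labelled RNG streams", {
  cfg <- synthetic_config(n_genes = 40L,
                          network_model = list(model = "erdos_renyi", p = 0.1),
                          n_sets = 4L, set_size_range = c(3L, 6L),
                          n_seeds = 5L, rng_seed = 99L)
  uni <- synthetic_universe(40L)
  sets_alone <- gen_gene_sets(cfg, uni)
  invisible(gen_network(cfg))  # an extra call must not shift other draws
  sets_after <- gen_gene_sets(cfg, uni)
  expect_identical(sets_alone, sets_after)
})

test_that("simulate_inputs writes a reloadable, manifest-documented bundle", {
  out <- withr::local_tempdir()
  cfg <- synthetic_config(n_genes = 50L,
                          network_model = list(model = "erdos_renyi", p = 0.1),
                          n_sets = 5L, set_size_range = c(4L, 8L),
                          n_seeds = 6L, direct_q = 0.5, rng_seed = 17L)
  paths <- simulate_inputs(cfg, out)
  expect_true(all(file.exists(unlist(paths))))
  expect_equal(length(read_universe_tsv(paths$universe)), 50L)
  expect_equal(length(read_gmt(paths$gmt)$sets), 5L)
  expect_equal(length(read_universe_tsv(paths$seeds)), 6L)
  manifest <- yaml::read_yaml(paths$manifest)
  expect_equal(manifest$rng_seed, 17L)
  net <- read_edge_list_full(paths$network)
  expect_equal(length(net$nodes), 50L)
})
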