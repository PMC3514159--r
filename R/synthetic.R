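# Synthetic networks, gene-set collections and seed sets with known
# (planted or null) enrichment structure.  Every generator is a pure
# function of its configuration, including the RNG seed: each call consumes
# its own labelled RNG stream, so adding one generator call to a script
# never shifts another call's draws.

#' Configuration for the synthetic-data generators
#'
#' Defaults emulate the scale of a proteome-wide two-configuration Y2H
#' screen: a universe of 10,214 genes (one per gene of a ~12,200-ORF
#' collection), ~59 seed proteins, and a sparse interaction network with
#' mean degree around 8.  `direct_q` and `indirect_k_links` default to 0
#' (no planted signal).
#'
#' @param n_genes Universe size.
#' @param network_model List: either `list(model = "erdos_renyi", p = ...)`
#'   or `list(model = "configuration", gamma = ..., min_degree = ...,
#'   max_degree = ...)` for a heavy-tailed degree sequence.
#' @param n_sets Number of gene sets.
#' @param set_size_range Integer `c(min, max)` set sizes.
#' @param n_seeds Seed-set size.
#' @param direct_q Fraction of seeds drawn from the planted term.
#' @param indirect_k_links Extra seed-to-pathway edges per seed.
#' @param rng_seed Integer seed.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 10214L,
                             network_model = list(model = "erdos_renyi",
                                                  p = 8 / (10214 - 1)),
                             n_sets = 40L,
                             set_size_range = c(30L, 60L),
                             n_seeds = 59L,
                             direct_q = 0,
                             indirect_k_links = 0L,
                             rng_seed = 1L) {
  stopifnot(n_genes >= 2L, direct_q >= 0, direct_q <= 1,
            length(set_size_range) == 2L,
            set_size_range[1L] >= 1L, set_size_range[2L] <= n_genes,
            set_size_range[1L] <= set_size_range[2L],
            n_seeds <= n_genes, indirect_k_links >= 0L)
  structure(list(n_genes = as.integer(n_genes),
                 network_model = network_model,
                 n_sets = as.integer(n_sets),
                 set_size_range = as.integer(set_size_range),
                 n_seeds = as.integer(n_seeds),
                 direct_q = direct_q,
                 indirect_k_links = as.integer(indirect_k_links),
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_config")
}

#' Gene identifiers of the synthetic universe
#' @param n Universe size.
#' @return Character vector `g00001 ...`.
#' @export
synthetic_universe <- function(n) sprintf("g%05d", seq_len(n))

#' Generate a synthetic undirected PPI network
#'
#' Erdős–Rényi G(n, p) or a configuration-model graph with a truncated
#' power-law degree sequence (degree sum forced even).  The result is a
#' simple graph over the full universe; isolated nodes are kept.
#'
#' @param cfg A [synthetic_config()].
#' @return A [ppi_network()].
#' @export
gen_network <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  genes <- synthetic_universe(cfg$n_genes)
  nm <- cfg$network_model
  g <- with_stream(cfg$rng_seed, "gen_network", {
    if (nm$model == "erdos_renyi") {
      igraph::sample_gnp(cfg$n_genes, nm$p)
    } else if (nm$model == "configuration") {
      ks <- seq.int(nm$min_degree, nm$max_degree)
      deg <- sample(ks, cfg$n_genes, replace = TRUE,
                    prob = ks^(-nm$gamma))
      if (sum(deg) %% 2L == 1L) {
        i <- which(deg < nm$max_degree)[1L]
        if (is.na(i)) stop("infeasible degree sequence (cannot even the sum)")
        deg[i] <- deg[i] + 1L
      }
      igraph::sample_degseq(deg, method = "fast.heur.simple")
    } else {
      stop("unknown network model: ", nm$model)
    }
  })
  el <- igraph::as_edgelist(g, names = FALSE)
  ppi_network(cbind(genes[el[, 1L]], genes[el[, 2L]]), nodes = genes)
}

#' Generate a synthetic gene-set collection
#'
#' `n_sets` sets with sizes uniform on `set_size_range` and members drawn
#' uniformly without replacement from the universe; sets may overlap.
#'
#' @param cfg A [synthetic_config()].
#' @param universe Character vector of gene identifiers.
#' @return A [gene_set_collection()] with source `"synthetic"`.
#' @export
gen_gene_sets <- function(cfg, universe) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_stream(cfg$rng_seed, "gen_gene_sets", {
    sizes <- sample(seq.int(cfg$set_size_range[1L], cfg$set_size_range[2L]),
                    cfg$n_sets, replace = TRUE)
    sets <- lapply(seq_len(cfg$n_sets), function(i) {
      list(name = sprintf("synthetic set %d", i),
           members = sample(universe, sizes[[i]]))
    })
    names(sets) <- sprintf("S%03d", seq_len(cfg$n_sets))
    gene_set_collection("synthetic", sets)
  })
}

#' Plant direct enrichment into a seed set
#'
#' Draws `ceiling(direct_q * n_seeds)` seeds uniformly from the planted
#' term and the remainder uniformly from the rest of the universe, without
#' duplicates, creating the over-representation signal that direct
#' enrichment must recover.
#'
#' @param cfg A [synthetic_config()].
#' @param universe Character vector of gene identifiers.
#' @param term_members Members of the planted term.
#' @return Character vector of `n_seeds` seed genes.
#' @export
plant_direct <- function(cfg, universe, term_members) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n_in <- ceiling(cfg$direct_q * cfg$n_seeds)
  term_members <- intersect(term_members, universe)
  if (n_in > length(term_members))
    stop("infeasible quota: ", n_in, " seeds requested from a term of ",
         length(term_members), " members")
  with_stream(cfg$rng_seed, "plant_direct", {
    inside <- sample(term_members, n_in)
    rest <- setdiff(universe, term_members)
    outside <- sample(rest, cfg$n_seeds - n_in)
    sample(c(inside, outside))
  })
}

#' Plant indirect enrichment into a network
#'
#' Returns a copy of the network with, per seed, `indirect_k_links` new
#' edges to distinct uniformly drawn pathway members (already-existing
#' edges are skipped and resampled among the remaining non-adjacent
#' members).  No edge is ever removed and the node set is unchanged.
#'
#' @param cfg A [synthetic_config()].
#' @param network A [ppi_network()].
#' @param pathway_members Members of the planted pathway.
#' @param seeds Seed genes receiving the extra edges.
#' @return A [ppi_network()] with the added edges.
#' @export
plant_indirect <- function(cfg, network, pathway_members, seeds) {
  stopifnot(inherits(cfg, "synthetic_config"),
            inherits(network, "ppi_network"))
  k <- cfg$indirect_k_links
  if (k > length(pathway_members))
    stop("indirect_k_links (", k, ") exceeds the pathway size (",
         length(pathway_members), ")")
  if (k == 0L) return(network)
  nbr <- new.env(parent = emptyenv())
  apply(network$edges, 1L, function(e) {
    assign(e[[1L]], c(get0(e[[1L]], nbr, ifnotfound = character()), e[[2L]]),
           envir = nbr)
    assign(e[[2L]], c(get0(e[[2L]], nbr, ifnotfound = character()), e[[1L]]),
           envir = nbr)
  })
  new_edges <- with_stream(cfg$rng_seed, "plant_indirect", {
    do.call(rbind, lapply(seeds, function(s) {
      cand <- setdiff(pathway_members,
                      c(s, get0(s, nbr, ifnotfound = character())))
      take <- min(k, length(cand))
      if (take == 0L) return(NULL)
      cbind(s, sample(cand, take))
    }))
  })
  ppi_network(rbind(network$edges, new_edges), nodes = network$nodes)
}

#' Write the synthetic inputs of one configuration to a directory
#'
#' Emits a universe TSV, an edge list, a GMT file, a seeds TSV and a YAML
#' manifest echoing the full configuration, so a run can be reproduced from
#' its files alone.
#'
#' @param cfg A [synthetic_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the named list of written paths.
#' @export
simulate_inputs <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "synthetic_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  universe <- synthetic_universe(cfg$n_genes)
  net <- gen_network(cfg)
  sets <- gen_gene_sets(cfg, universe)
  term <- sets$sets[[1L]]$members
  seeds <- plant_direct(cfg, universe, term)
  # indirect signal goes into the second set: seeds are excluded from the
  # second-degree set, so planting it into the direct term would erase it
  if (cfg$indirect_k_links > 0L && cfg$n_sets >= 2L)
    net <- plant_indirect(cfg, net, sets$sets[[2L]]$members, seeds)
  paths <- list(
    universe = file.path(out_dir, "universe.tsv"),
    network = file.path(out_dir, "network.tsv"),
    gmt = file.path(out_dir, "gene_sets.gmt"),
    seeds = file.path(out_dir, "seeds.tsv"),
    manifest = file.path(out_dir, "manifest.yaml")
  )
  writeLines(c("gene", universe), paths$universe)
  write_edge_list(net, paths$network)
  writeLines(vapply(names(sets$sets), function(id) {
    paste(c(id, sets$sets[[id]]$name, sets$sets[[id]]$members),
          collapse = "\t")
  }, character(1)), paths$gmt)
  writeLines(c("gene", seeds), paths$seeds)
  yaml::write_yaml(unclass(cfg), paths$manifest)
  invisible(paths)
}
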