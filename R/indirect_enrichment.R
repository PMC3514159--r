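# Second-degree interactor expansion and the seed-randomization permutation
# null with empirical FDR and per-source Bonferroni correction.

#' Permutation-null configuration
#'
#' @param n_trials Number of randomized seed sets (default 100,000).
#' @param rng_seed Integer seed; the whole run is reproducible from it.
#' @param sampling `"uniform"`: each trial draws seed-count nodes uniformly
#'   without replacement from the network; `"degree_matched"`: each true
#'   seed is replaced by a node from the same log2 degree bin, so hub bias
#'   of the real seeds is preserved in the null.
#' @param smoothing `"none"` gives the literal exceedance proportion `r/N`
#'   (which can be exactly 0); `"add_one"` gives `(r+1)/(N+1)` for
#'   downstream log-scale use.
#' @param alpha Significance level on the corrected FDR (default 0.05).
#' @param min_obs Minimum observed indirect targets for a pathway to be
#'   called significant (default 2).
#' @return Object of class `permutation_config`.
#' @export
permutation_config <- function(n_trials = 100000L, rng_seed = 1L,
                               sampling = c("uniform", "degree_matched"),
                               smoothing = c("none", "add_one"),
                               alpha = 0.05, min_obs = 2L) {
  n_trials <- as.integer(n_trials)
  stopifnot(n_trials >= 1L, alpha > 0, alpha < 1)
  structure(list(n_trials = n_trials, rng_seed = as.integer(rng_seed),
                 sampling = match.arg(sampling),
                 smoothing = match.arg(smoothing),
                 alpha = alpha, min_obs = as.integer(min_obs)),
            class = "permutation_config")
}

#' Second-degree interactor set
#'
#' Union of the network neighbors of all in-network seeds, minus the seeds
#' themselves and minus the bait.  Self-loops contribute nothing.  Seeds
#' absent from the network are dropped with a warning; if no seed is in the
#' network this is an error, while all-in-network seeds being isolated
#' yields an empty set with a warning.
#'
#' @param network A [ppi_network()].
#' @param seeds Character vector of direct-interactor genes.
#' @param bait Optional bait gene identifier, excluded from the expansion.
#' @return Sorted character vector of indirect-interactor genes.
#' @export
second_degree <- function(network, seeds, bait = NULL) {
  stopifnot(inherits(network, "ppi_network"))
  seeds <- unique(seeds)
  present <- seeds[seeds %in% network$nodes]
  if (length(present) == 0L)
    stop("none of the ", length(seeds), " seeds is present in the network")
  absent <- length(seeds) - length(present)
  if (absent > 0L)
    warning(absent, " seed(s) absent from the network were dropped")
  adj <- network_adjacency(network)
  idx <- match(present, network$nodes)
  nb <- unique(unlist(adj[idx], use.names = FALSE))
  out <- setdiff(network$nodes[nb], c(seeds, bait))
  if (length(out) == 0L)
    warning("second-degree expansion is empty (all in-network seeds are ",
            "isolated or connect only to seeds/bait)")
  sort(out)
}

#' Observed per-pathway counts of indirect targets
#'
#' @param indirect Character vector of indirect-interactor genes.
#' @param collection A [gene_set_collection()].
#' @return Named integer vector: distinct indirect targets per pathway.
#' @export
observed_pathway_counts <- function(indirect, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  vapply(collection$sets,
         function(s) length(intersect(indirect, s$members)),
         integer(1))
}

#' Sample randomized seed sets for the permutation null
#'
#' Each trial draws a set of `k` network nodes: uniformly without
#' replacement (`sampling = "uniform"`), or matched to the degrees of the
#' true seeds by log2 degree bins (`sampling = "degree_matched"`, which
#' requires `seeds`).  Draws are fully reproducible from `cfg$rng_seed`.
#'
#' @param network A [ppi_network()].
#' @param k Seed-set size; must not exceed the node count.
#' @param cfg A [permutation_config()].
#' @param seeds True seed genes; required for degree-matched sampling.
#' @return Integer matrix (`k` rows, `n_trials` columns) of node indices
#'   into `network$nodes`, with the node vector attached as attribute
#'   `"nodes"`.  `as.list()` converts it to a list of gene-identifier sets.
#' @export
sample_null_seed_sets <- function(network, k, cfg, seeds = NULL) {
  stopifnot(inherits(network, "ppi_network"),
            inherits(cfg, "permutation_config"))
  n <- length(network$nodes)
  k <- as.integer(k)
  if (k > n) stop("k (", k, ") exceeds the number of network nodes (", n, ")")
  if (k < 1L) stop("k must be at least 1")
  trials <- with_stream(cfg$rng_seed, "null_seeds", {
    if (cfg$sampling == "uniform") {
      vapply(seq_len(cfg$n_trials), function(i) sample.int(n, k), integer(k))
    } else {
      if (is.null(seeds)) stop("degree_matched sampling requires the true seeds")
      deg <- lengths(network_adjacency(network))
      bin <- pmin(floor(log2(pmax(deg, 1L))), 30)
      bin[deg == 0L] <- -1L
      seed_idx <- match(intersect(unique(seeds), network$nodes),
                        network$nodes)
      if (length(seed_idx) != k)
        stop("degree-matched sampling needs exactly k in-network seeds")
      pool <- split(seq_len(n), bin)
      vapply(seq_len(cfg$n_trials), function(i) {
        draw <- integer(0)
        for (b in bin[seed_idx]) {
          cand <- setdiff(pool[[as.character(b)]], draw)
          if (length(cand) == 0L)
            stop("degree bin exhausted during degree-matched sampling")
          draw <- c(draw, cand[sample.int(length(cand), 1L)])
        }
        draw
      }, integer(k))
    }
  })
  trials <- matrix(trials, nrow = k)
  attr(trials, "nodes") <- network$nodes
  class(trials) <- c("null_seed_sets", class(trials))
  trials
}

#' @export
as.list.null_seed_sets <- function(x, ...) {
  nodes <- attr(x, "nodes")
  lapply(seq_len(ncol(x)), function(j) nodes[x[, j]])
}

#' Empirical false discovery rate of an observed pathway count
#'
#' The exceedance proportion of the permutation null: the fraction of
#' randomized trials whose pathway count is at least the observed count.
#'
#' @param obs Observed number of indirect targets in the pathway.
#' @param null_counts Integer vector of per-trial null counts (non-empty).
#' @param smoothing `"none"` for `r/N`, `"add_one"` for `(r+1)/(N+1)`.
#' @return Probability in `[0, 1]`.
#' @export
empirical_fdr <- function(obs, null_counts, smoothing = c("none", "add_one")) {
  smoothing <- match.arg(smoothing)
  if (length(null_counts) == 0L) stop("null_counts is empty")
  r <- sum(null_counts >= obs)
  N <- length(null_counts)
  if (smoothing == "none") r / N else (r + 1) / (N + 1)
}

#' Bonferroni correction
#'
#' @param p Probability (or probability-like empirical FDR).
#' @param m Positive integer number of tests.
#' @return `min(1, p * m)`, vectorized over `p`.
#' @export
bonferroni_correct <- function(p, m) {
  stopifnot(all(p >= 0 & p <= 1), m >= 1)
  pmin(1, p * m)
}

# Null pathway-count matrix: expands every trial column of `trials` with the
# same bait exclusion as second_degree and counts distinct members per
# pathway.  members_idx: list of integer node-index vectors (one per tested
# pathway).  Thin wrapper around the compiled kernel.
null_pathway_count_matrix <- function(adj, members_idx, trials, bait_idx, n) {
  counts <- cpp_null_pathway_counts(adj, members_idx,
                                    matrix(as.integer(trials),
                                           nrow = nrow(trials)),
                                    as.integer(bait_idx), as.integer(n))
  counts
}

#' Indirect-target enrichment with a seed-randomization null
#'
#' For each pathway with at least one member in the network, the observed
#' count of distinct second-degree interactors is compared to its
#' distribution over `cfg$n_trials` randomized seed sets (each expanded with
#' the same bait and seed exclusions).  The empirical FDR is the exceedance
#' proportion; Bonferroni correction is applied per source collection with
#' `m` equal to the number of pathways tested in that source.  A pathway is
#' significant when its corrected FDR is below `cfg$alpha` and at least
#' `cfg$min_obs` indirect targets were observed.  The odds ratio uses the
#' network node set as background: cells `(obs, |indirect| - obs,
#' |pathway in network| - obs, remainder)` with the Haldane zero-cell
#' correction.
#'
#' @param network A [ppi_network()].
#' @param seeds Character vector of direct-interactor genes.
#' @param bait Optional bait gene identifier.
#' @param collections A [gene_set_collection()] or list of them (one per
#'   source).
#' @param cfg A [permutation_config()].
#' @return Data frame sorted by empirical FDR then pathway id, with columns
#'   `pathway_id`, `name`, `source`, `obs`, `odds_ratio`, `null_mean`,
#'   `empirical_fdr`, `corrected_fdr`, `significant` and list-column
#'   `member_hits`; attribute `m_per_source` records the per-source test
#'   counts.
#' @export
run_indirect_enrichment <- function(network, seeds, bait = NULL, collections,
                                    cfg = permutation_config()) {
  stopifnot(inherits(network, "ppi_network"),
            inherits(cfg, "permutation_config"))
  if (inherits(collections, "gene_set_collection"))
    collections <- list(collections)
  stopifnot(length(collections) >= 1L)
  nodes <- network$nodes
  n <- length(nodes)
  adj <- network_adjacency(network)
  indirect <- second_degree(network, seeds, bait)
  seeds_in <- intersect(unique(seeds), nodes)
  k <- length(seeds_in)
  trials <- sample_null_seed_sets(network, k, cfg,
                                  seeds = if (cfg$sampling ==
                                              "degree_matched") seeds)
  bait_idx <- if (!is.null(bait) && bait %in% nodes) match(bait, nodes) else 0L

  per_source <- lapply(collections, function(col) {
    tested <- Filter(function(s) any(s$members %in% nodes), col$sets)
    if (length(tested) == 0L) return(NULL)
    members_idx <- lapply(tested, function(s)
      match(intersect(s$members, nodes), nodes))
    counts <- null_pathway_count_matrix(adj, members_idx, trials, bait_idx, n)
    obs <- vapply(tested, function(s)
      length(intersect(indirect, s$members)), integer(1))
    fdr <- vapply(seq_along(tested), function(i)
      empirical_fdr(obs[[i]], counts[i, ], cfg$smoothing), numeric(1))
    m <- length(tested)
    corrected <- bonferroni_correct(fdr, m)
    or <- vapply(seq_along(tested), function(i) {
      n_path <- length(members_idx[[i]])
      odds_ratio(contingency_table(obs[[i]],
                                   length(indirect) - obs[[i]],
                                   n_path - obs[[i]],
                                   n - length(indirect) - n_path + obs[[i]]),
                 zero_cell_correction = TRUE)
    }, numeric(1))
    out <- data.frame(
      pathway_id = names(tested),
      name = vapply(tested, function(s) s$name, character(1)),
      source = col$source,
      obs = obs,
      odds_ratio = or,
      null_mean = rowMeans(counts),
      empirical_fdr = fdr,
      corrected_fdr = corrected,
      significant = corrected < cfg$alpha & obs >= cfg$min_obs,
      stringsAsFactors = FALSE, row.names = NULL
    )
    out$member_hits <- lapply(tested, function(s)
      sort(intersect(indirect, s$members)))
    attr(out, "m") <- m
    out
  })
  per_source <- Filter(Negate(is.null), per_source)
  if (length(per_source) == 0L)
    stop("no pathway of any collection has members in the network")
  m_per_source <- vapply(per_source, function(x) attr(x, "m"), integer(1))
  names(m_per_source) <- vapply(per_source, function(x) x$source[[1L]],
                                character(1))
  res <- do.call(rbind, per_source)
  res <- res[order(res$empirical_fdr, res$pathway_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "m_per_source") <- m_per_source
  attr(res, "config") <- cfg
  res
}
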