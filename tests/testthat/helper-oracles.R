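# Independent oracles and small in-code fixtures shared across test files.

# Upper-tail hypergeometric probability by explicit enumeration over the
# support: sum of C(K,x) C(N-K, n-x) / C(N,n) for x >= a.  Independent of
# the distribution functions used by the implementation.
hyper_tail_enum <- function(a, b, c, d) {
  N <- a + b + c + d
  K <- a + c
  n <- a + b
  xs <- seq.int(a, min(K, n))
  if (length(xs) == 0L || a > min(K, n)) return(0)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Exhaustive exceedance proportion over ALL C(n, k) seed subsets of a small
# network, built from first principles (neighbor unions on a named edge
# list), independent of the package's expansion code.
exhaustive_exceedance <- function(edges, nodes, k, pathway, obs, bait = NULL) {
  nbrs <- lapply(nodes, function(v) {
    unique(c(edges[edges[, 1] == v & edges[, 2] != v, 2],
             edges[edges[, 2] == v & edges[, 1] != v, 1]))
  })
  names(nbrs) <- nodes
  combos <- utils::combn(nodes, k, simplify = FALSE)
  counts <- vapply(combos, function(ss) {
    ind <- setdiff(unique(unlist(nbrs[ss])), c(ss, bait))
    length(intersect(ind, pathway))
  }, integer(1))
  list(counts = counts, exceedance = mean(counts >= obs))
}

# Build a screen_hits data frame in code (no file), mirroring the fixture
# columns after parsing.
make_hits <- function(symbols, config = "DB",
                      copur = rep("Y", length(symbols)),
                      bifc = rep("Nuclear", length(symbols)),
                      entrez = seq_along(symbols) + 1000L,
                      prev = rep(FALSE, length(symbols))) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  lines <- c(
    paste(c("symbol", "entrez_id", "uniprot_acc", "name", "function_note",
            "configs", "previously_described", "copurification", "bifc"),
          collapse = "\t"),
    vapply(seq_along(symbols), function(i) {
      paste(c(symbols[[i]], entrez[[i]], sprintf("P%05d", entrez[[i]]),
              paste(symbols[[i]], "protein"), "none", config,
              if (prev[[i]]) "1" else "0", copur[[i]], bifc[[i]]),
            collapse = "\t")
    }, character(1))
  )
  writeLines(lines, tmp)
  read_screen_tsv(tmp)
}

load_fixture_catalog <- function() {
  db <- read_screen_tsv(se_example("hoxa1_db_screen.tsv"))
  ad <- read_screen_tsv(se_example("hoxa1_ad_screen.tsv"))
  list(db = db, ad = ad,
       catalog = merge_screens(db, ad, protein_ref("HOXA1", 3198L, "P49639")))
}

# Published-table fixtures with ranks assigned by ascending raw p.
load_published_go <- function() {
  g <- read_enrichment_tsv(se_example("go_enrichment_published.tsv"))
  ord <- order(g$p_value, g$term)
  g$rank <- integer(nrow(g))
  g$rank[ord] <- seq_len(nrow(g))
  g
}

load_published_pathways <- function() {
  read_enrichment_tsv(se_example("pathway_enrichment_published.tsv"))
}
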