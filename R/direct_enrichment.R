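# Fisher-exact enrichment of the direct interactor (seed) set against
# gene-set collections, restricted to the tested universe, with the
# published screen report's multiple-testing dialect.

#' Construct a 2x2 contingency table for gene-set enrichment
#'
#' Cells: `a` seeds annotated to the term, `b` seeds not annotated, `c`
#' non-seed universe genes annotated, `d` the remainder, so that
#' `a + b = |seeds %in% universe|` and `a + b + c + d = |universe|`.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return Object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("contingency cells must be non-negative integers")
  storage.mode(cells) <- "integer"
  structure(as.list(cells), class = "contingency_table")
}

#' Build the contingency table for one term
#'
#' Seeds and term members are intersected with the universe before counting;
#' genes outside the tested universe never contribute to any cell.
#'
#' @param seeds Character vector of seed (direct interactor) genes.
#' @param term_members Character vector of the term's annotated genes.
#' @param universe Character vector: the tested gene universe.
#' @return A [contingency_table()].
#' @export
build_contingency <- function(seeds, term_members, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("universe is empty")
  s <- unique(intersect(seeds, universe))
  if (length(s) == 0L) stop("no seed lies in the universe: nothing testable")
  t <- unique(intersect(term_members, universe))
  a <- length(intersect(s, t))
  contingency_table(a, length(s) - a, length(t) - a,
                    length(universe) - length(s) - length(t) + a)
}

#' One-sided Fisher exact test (enrichment)
#'
#' Upper-tail hypergeometric probability `P(X >= a)` of drawing at least `a`
#' annotated genes when `n = a + b` genes are drawn without replacement from
#' a universe of `N = a + b + c + d` genes of which `K = a + c` are
#' annotated.  Only over-representation is tested.
#'
#' @param t A [contingency_table()].
#' @return The upper-tail probability.
#' @export
fisher_one_sided <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  N <- t$a + t$b + t$c + t$d
  K <- t$a + t$c
  n <- t$a + t$b
  stats::phyper(t$a - 1L, K, N - K, n, lower.tail = FALSE)
}

#' Sample odds ratio with optional Haldane-Anscombe correction
#'
#' `(a*d)/(b*c)`; when any cell is zero and `zero_cell_correction` is on,
#' 0.5 is added to all four cells before the ratio is formed.
#'
#' @param t A [contingency_table()].
#' @param zero_cell_correction Apply the 0.5 correction when a cell is zero?
#' @return Positive real odds ratio.
#' @export
odds_ratio <- function(t, zero_cell_correction = TRUE) {
  stopifnot(inherits(t, "contingency_table"))
  a <- t$a; b <- t$b; cc <- t$c; d <- t$d
  if (any(c(a, b, cc, d) == 0L)) {
    if (!zero_cell_correction) {
      if (b * cc == 0L)
        stop("odds ratio is infinite (zero cell) and correction is disabled")
    } else {
      a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
    }
  }
  (a * d) / (b * cc)
}

#' Multiple-testing correction configuration
#'
#' @param mode `"paper_simple"` reproduces the dialect of published screen
#'   reports: `corrected_i = min(1, p_i * m / rank_i)` with ranks by
#'   ascending p and **no** step-up monotonization, so corrected values need
#'   not be monotone in rank.  `"standard_bh"` is the usual Benjamini-
#'   Hochberg step-up with a cumulative minimum from the largest rank.
#' @param m Number of tests; `NULL` means "number of p-values corrected"
#'   (for [run_direct_enrichment()], the number of tested terms).
#' @return Object of class `correction_config`.
#' @export
correction_config <- function(mode = c("paper_simple", "standard_bh"),
                              m = NULL) {
  mode <- match.arg(mode)
  if (!is.null(m)) {
    m <- as.integer(m)
    stopifnot(!is.na(m), m >= 1L)
  }
  structure(list(mode = mode, m = m), class = "correction_config")
}

#' Correct a vector of p-values for multiple testing
#'
#' Ranks are assigned by ascending p with ties broken by `ids` so that ranks
#' (and therefore `paper_simple` output) are reproducible.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param cfg A [correction_config()]; `cfg$m` must be at least `length(p)`.
#' @param ids Tie-breaking identifiers, defaults to the input positions.
#' @return Data frame with columns `rank` and `corrected`, aligned to the
#'   input order.
#' @export
multiple_test_correct <- function(p, cfg = correction_config(),
                                  ids = as.character(seq_along(p))) {
  stopifnot(inherits(cfg, "correction_config"),
            all(p >= 0 & p <= 1), length(ids) == length(p))
  m <- cfg$m %||% length(p)
  if (m < length(p))
    stop("m (", m, ") is smaller than the number of p-values (",
         length(p), ")")
  ord <- order(p, ids)
  rank <- integer(length(p))
  rank[ord] <- seq_along(p)
  if (cfg$mode == "paper_simple") {
    corrected <- pmin(1, p * m / rank)
  } else {
    sorted <- p[ord] * m / seq_along(p)
    sorted <- rev(cummin(rev(sorted)))
    corrected <- numeric(length(p))
    corrected[ord] <- pmin(1, sorted)
  }
  data.frame(rank = rank, corrected = corrected)
}

#' Infer the implicit test count from printed corrected/raw pairs
#'
#' Published tables print raw and corrected values but not the number of
#' tests; the multiplier is recoverable because `corrected = p * m / rank`
#' (simple dialect) or `corrected = p * m` (Bonferroni).  Returns the
#' per-row rounded estimate; a consistent table yields one unique value.
#'
#' @param p Raw p-values (or empirical FDRs).
#' @param corrected Printed corrected values.
#' @param rank Optional rank vector for the simple `p*m/rank` dialect; when
#'   `NULL` a plain Bonferroni multiplier is inferred.
#' @return Integer vector of per-row `m` estimates.
#' @export
infer_test_count <- function(p, corrected, rank = NULL) {
  stopifnot(length(p) == length(corrected), all(p > 0))
  if (is.null(rank)) rank <- rep(1, length(p))
  as.integer(round(corrected * rank / p))
}

#' Direct-target gene-set enrichment
#'
#' Every term with at least one member in the universe is tested with the
#' one-sided Fisher exact test; `m` defaults to the number of such tested
#' terms (callers may pin it via `cfg`).  Ranks and corrected values are
#' assigned over all tested terms, then the report is filtered to terms with
#' at least `min_obs` annotated seeds and sorted by ascending p (ties by
#' term id).
#'
#' @param seeds Character vector of direct-interactor genes.
#' @param collection A [gene_set_collection()].
#' @param universe Character vector: the tested gene universe.
#' @param min_obs Minimum number of annotated seeds for a term to be
#'   reported (default 2).
#' @param cfg A [correction_config()].
#' @return Data frame with columns `term_id`, `name`, `obs`, `odds_ratio`,
#'   `p`, `p_corrected`, `rank`; attribute `m` records the test count.
#' @export
run_direct_enrichment <- function(seeds, collection, universe, min_obs = 2L,
                                  cfg = correction_config()) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(collection$sets) == 0L) stop("empty gene-set collection")
  universe <- unique(universe)
  if (length(intersect(seeds, universe)) == 0L)
    stop("no seed lies in the universe")
  tested <- Filter(function(s) length(intersect(s$members, universe)) > 0L,
                   collection$sets)
  if (length(tested) == 0L) {
    out <- data.frame(term_id = character(), name = character(),
                      obs = integer(), odds_ratio = numeric(),
                      p = numeric(), p_corrected = numeric(),
                      rank = integer())
    attr(out, "m") <- 0L
    return(out)
  }
  tabs <- lapply(tested, function(s)
    build_contingency(seeds, s$members, universe))
  res <- data.frame(
    term_id = names(tested),
    name = vapply(tested, function(s) s$name, character(1)),
    obs = vapply(tabs, function(t) t$a, integer(1)),
    odds_ratio = vapply(tabs, odds_ratio, numeric(1)),
    p = vapply(tabs, fisher_one_sided, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (is.null(cfg$m)) cfg <- correction_config(cfg$mode, length(tested))
  corr <- multiple_test_correct(res$p, cfg, ids = res$term_id)
  res$p_corrected <- corr$corrected
  res$rank <- corr$rank
  res <- res[res$obs >= min_obs, , drop = FALSE]
  res <- res[order(res$p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "m") <- cfg$m
  res
}
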