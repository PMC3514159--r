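# End-to-end orchestration: catalog loading, direct and indirect enrichment,
# deterministic report files and a run log sufficient to reproduce a run.

#' Assemble a pipeline run configuration
#'
#' A flat key-value configuration; every effective value is echoed to the
#' run log so the stochastic stage is auditable.  All stages are optional:
#' the catalog stage runs when `catalog_db` is set, the direct stage when
#' `gmt` and `universe` are set, and the indirect stage when `gmt` and
#' `network` are set.
#'
#' @param out_dir Output directory (created if needed).
#' @param catalog_db,catalog_ad Paths to screen hit TSV fixtures.
#' @param bait_symbol,bait_entrez Bait identity for the catalog stage.
#' @param seeds Path to a one-column seed gene list (defaults to the
#'   catalog's partner genes for the enrichment stages when a catalog is
#'   loaded).
#' @param universe Path to a one-column universe list.
#' @param network Path to an edge-list file.
#' @param gmt Named character vector of GMT paths; names are the source
#'   labels (unnamed entries get source `"GMT"`).
#' @param bait_gene Gene identifier of the bait in the enrichment
#'   namespace, excluded from second-degree expansion.
#' @param direct A [correction_config()].
#' @param perm A [permutation_config()].
#' @param min_obs Direct-stage reporting threshold.
#' @param verbosity 0 = quiet, 1 = stage messages.
#' @return Object of class `run_config`.
#' @export
run_config <- function(out_dir,
                       catalog_db = NULL, catalog_ad = NULL,
                       bait_symbol = NULL, bait_entrez = NULL,
                       seeds = NULL, universe = NULL, network = NULL,
                       gmt = NULL, bait_gene = NULL,
                       direct = correction_config(),
                       perm = permutation_config(),
                       min_obs = 2L, verbosity = 0L) {
  structure(list(out_dir = out_dir, catalog_db = catalog_db,
                 catalog_ad = catalog_ad, bait_symbol = bait_symbol,
                 bait_entrez = bait_entrez, seeds = seeds,
                 universe = universe, network = network, gmt = gmt,
                 bait_gene = bait_gene, direct = direct, perm = perm,
                 min_obs = as.integer(min_obs),
                 verbosity = as.integer(verbosity)),
            class = "run_config")
}

.stage <- function(label, verbosity, code) {
  if (verbosity > 0L) message("[", label, "] ...")
  tryCatch(code, error = function(e) {
    stop("stage '", label, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Writes `catalog_summary.tsv` and `localization_tally.tsv` (catalog
#' stage), `direct_enrichment.tsv` (direct stage),
#' `indirect_enrichment.tsv` (indirect stage) and `run_log.yaml` into
#' `cfg$out_dir`.  Outputs are identical for identical configurations; on a
#' stage error all partial outputs of this run are removed and the error is
#' re-raised with a stage label.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a named list with the loaded catalog and the result
#'   tables.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  for (p in c(cfg$catalog_db, cfg$catalog_ad, cfg$seeds, cfg$universe,
              cfg$network, unname(cfg$gmt))) {
    if (!file.exists(p)) stop("input path does not exist: ", p)
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  t0 <- proc.time()[["elapsed"]]
  on_fail <- function(e) {
    unlink(written)
    stop(e)
  }
  result <- tryCatch({
    out <- list()
    log <- list(parameters = list(
      catalog_db = cfg$catalog_db, catalog_ad = cfg$catalog_ad,
      seeds = cfg$seeds, universe = cfg$universe, network = cfg$network,
      gmt = as.list(cfg$gmt %||% character()),
      bait_gene = cfg$bait_gene, min_obs = cfg$min_obs,
      correction = unclass(cfg$direct),
      permutation = unclass(cfg$perm)
    ))

    seeds <- if (!is.null(cfg$seeds)) read_universe_tsv(cfg$seeds)

    if (!is.null(cfg$catalog_db)) {
      out$catalog <- .stage("catalog", cfg$verbosity, {
        db <- read_screen_tsv(cfg$catalog_db)
        ad <- if (!is.null(cfg$catalog_ad)) read_screen_tsv(cfg$catalog_ad)
        bait <- protein_ref(cfg$bait_symbol, cfg$bait_entrez)
        merge_screens(db, ad, bait)
      })
      summary_path <- file.path(cfg$out_dir, "catalog_summary.tsv")
      tally_path <- file.path(cfg$out_dir, "localization_tally.tsv")
      written <- c(written, summary_path, tally_path)
      smry <- rbind(
        cbind(include_bait_self = FALSE,
              summarize_counts(out$catalog, include_bait_self = FALSE)),
        cbind(include_bait_self = TRUE,
              summarize_counts(out$catalog, include_bait_self = TRUE))
      )
      write_enrichment_tsv(smry, summary_path)
      write_enrichment_tsv(tally_localization(out$catalog), tally_path)
      log$catalog <- list(n_db = sum(out$catalog$records$config_db),
                          n_ad = sum(out$catalog$records$config_ad))
    }

    gmts <- if (!is.null(cfg$gmt)) .stage("gene_sets", cfg$verbosity, {
      labels <- names(cfg$gmt) %||% rep("", length(cfg$gmt))
      labels[!nzchar(labels)] <- "GMT"
      lapply(seq_along(cfg$gmt), function(i)
        read_gmt(cfg$gmt[[i]], source = labels[[i]]))
    })

    if (!is.null(gmts) && !is.null(cfg$universe)) {
      out$direct <- .stage("direct_enrichment", cfg$verbosity, {
        if (is.null(seeds)) stop("direct stage needs a seeds file")
        universe <- read_universe_tsv(cfg$universe)
        do.call(rbind, lapply(gmts, function(g)
          run_direct_enrichment(seeds, g, universe,
                                min_obs = cfg$min_obs, cfg = cfg$direct)))
      })
      direct_path <- file.path(cfg$out_dir, "direct_enrichment.tsv")
      written <- c(written, direct_path)
      write_enrichment_tsv(out$direct, direct_path)
    }

    if (!is.null(gmts) && !is.null(cfg$network)) {
      out$indirect <- .stage("indirect_enrichment", cfg$verbosity, {
        if (is.null(seeds)) stop("indirect stage needs a seeds file")
        net <- read_edge_list_full(cfg$network)
        run_indirect_enrichment(net, seeds, bait = cfg$bait_gene,
                                collections = gmts, cfg = cfg$perm)
      })
      indirect_path <- file.path(cfg$out_dir, "indirect_enrichment.tsv")
      written <- c(written, indirect_path)
      write_enrichment_tsv(out$indirect, indirect_path)
      log$indirect <- list(
        rng_seed = cfg$perm$rng_seed,
        n_trials = cfg$perm$n_trials,
        m_per_source = as.list(attr(out$indirect, "m_per_source"))
      )
    }

    log$runtime_s <- round(proc.time()[["elapsed"]] - t0, 3)
    yaml::write_yaml(log, file.path(cfg$out_dir, "run_log.yaml"))
    out
  }, error = on_fail)
  invisible(result)
}

#' Packaged example file paths
#'
#' @param file File name under the package's `extdata`, or `NULL` to list
#'   all available files.
#' @return Full path(s).
#' @export
se_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "seedenrich"))
  } else {
    system.file("extdata", file, package = "seedenrich", mustWork = TRUE)
  }
}

#' Demo: reproduce the screen catalog counts from the packaged fixtures
#'
#' Loads the packaged two-configuration Hoxa1 screen hit tables, merges
#' them, and returns the headline counts under both homodimer conventions
#' together with the per-compartment localization tally.
#'
#' @return List with elements `catalog`, `counts_excl_bait`,
#'   `counts_incl_bait`, `tally`.
#' @export
demo_catalog <- function() {
  db <- read_screen_tsv(se_example("hoxa1_db_screen.tsv"))
  ad <- read_screen_tsv(se_example("hoxa1_ad_screen.tsv"))
  catalog <- merge_screens(db, ad, protein_ref("HOXA1", 3198L, "P49639"))
  list(catalog = catalog,
       n_db = nrow(db), n_ad = nrow(ad),
       counts_excl_bait = summarize_counts(catalog, FALSE),
       counts_incl_bait = summarize_counts(catalog, TRUE),
       tally = tally_localization(catalog, FALSE))
}
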