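# Readers and writers for gene-set collections, PPI networks, gene universes
# and enrichment result tables.  All identifiers live in a single
# caller-declared namespace (gene symbols for synthetic data, Entrez IDs for
# packaged fixtures); no cross-namespace mapping is attempted.

#' Construct a gene-set collection
#'
#' @param source Label for the collection's origin (e.g. `"GO"`, `"KEGG"`,
#'   `"NCI-Nature"`, `"Reactome"`, `"synthetic"`).
#' @param sets Named list; each element is a list with `name` (description
#'   string) and `members` (non-empty character vector of gene identifiers;
#'   deduplicated here).
#' @return Object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(source, sets) {
  stopifnot(is.character(source), length(source) == 1L, is.list(sets))
  if (length(sets) && (is.null(names(sets)) || anyDuplicated(names(sets))))
    stop("set term_ids must be unique and non-empty")
  sets <- lapply(sets, function(s) {
    members <- unique(as.character(s$members))
    if (length(members) == 0L) stop("gene set with empty member list")
    list(name = as.character(s$name %||% ""), members = members)
  })
  structure(list(source = source, sets = sets), class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- vapply(x$sets, function(s) length(s$members), integer(1))
  cat("<gene_set_collection>", x$source, "|", length(x$sets), "sets",
      if (length(sizes)) sprintf("| sizes %d-%d", min(sizes), max(sizes)),
      "\n")
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields `term_id`,
#' `description`, then one or more member identifiers.  Members are
#' deduplicated; a line with fewer than three fields is a format error
#' reported with its line number.
#'
#' @param path Path to a GMT file.
#' @param source Source label attached to the collection.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, source = "GMT") {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    f <- f[nzchar(f)]
    if (length(f) < 3L)
      stop("GMT format error at line ", i, ": fewer than 3 fields")
    sets[[f[[1L]]]] <- list(name = f[[2L]], members = unique(f[-(1:2)]))
  }
  gene_set_collection(source, sets)
}

#' Construct an undirected PPI network
#'
#' Edges are stored canonically (unordered pairs, deduplicated).  Self-loops
#' are permitted but marked: they are listed in the `self_loops` element and
#' never contribute neighbors during expansion.
#'
#' @param edges Two-column character matrix or data frame of endpoints; may
#'   have zero rows.
#' @param nodes Optional character vector of node identifiers; defaults to
#'   the endpoints seen in `edges`.  Must cover all endpoints.
#' @return Object of class `ppi_network` with elements `nodes`, `edges`
#'   (canonical two-column matrix) and `self_loops`.
#' @export
ppi_network <- function(edges, nodes = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (length(edges) == 0L) edges <- matrix(character(), ncol = 2L)
  storage.mode(edges) <- "character"
  if (ncol(edges) != 2L) stop("edges must have exactly two columns")
  a <- pmin(edges[, 1L], edges[, 2L])
  b <- pmax(edges[, 1L], edges[, 2L])
  keep <- !duplicated(paste(a, b, sep = "\r"))
  edges <- cbind(from = a[keep], to = b[keep])
  nodes <- sort(unique(c(nodes, edges)))
  if (length(nodes) == 0L) nodes <- character()
  structure(list(nodes = nodes, edges = edges,
                 self_loops = unique(edges[edges[, 1L] == edges[, 2L], 1L])),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("<ppi_network>", length(x$nodes), "nodes,", nrow(x$edges), "edges",
      if (length(x$self_loops)) sprintf("(%d self-loops)",
                                        length(x$self_loops)),
      "\n")
  invisible(x)
}

# Integer adjacency list over the node set, self-loops excluded.  Used by
# second-degree expansion and the permutation kernel.
network_adjacency <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  n <- length(net$nodes)
  i <- match(net$edges[, 1L], net$nodes)
  j <- match(net$edges[, 2L], net$nodes)
  keep <- i != j
  i <- i[keep]; j <- j[keep]
  adj <- split(c(j, i), factor(c(i, j), levels = seq_len(n)))
  names(adj) <- NULL
  lapply(adj, function(v) sort(unique(v)))
}

#' Read a two-column edge list
#'
#' Non-comment lines carry two tab- or space-separated identifiers.  The
#' graph is undirected: `A B` and `B A` collapse to one edge.  Lines starting
#' with `#` are skipped; self-loops are retained and flagged.
#'
#' @param path Path to the edge-list file.
#' @return A [ppi_network()].
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lines <- lines[keep]
  if (length(lines) == 0L) return(ppi_network(matrix(character(), ncol = 2)))
  fields <- strsplit(trimws(lines), "[\t ]+")
  bad <- which(lengths(fields) != 2L)
  if (length(bad))
    stop("edge-list format error at data line ", bad[[1L]],
         ": expected 2 fields, got ", length(fields[[bad[[1L]]]]))
  ppi_network(do.call(rbind, fields))
}

#' Write a network as a two-column edge list
#'
#' Isolated nodes are written as `# node <id>` comment lines so that
#' read-after-write is the identity on (nodes, edges).
#'
#' @param net A [ppi_network()].
#' @param path Output path.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "ppi_network"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  isolated <- setdiff(net$nodes, c(net$edges))
  if (length(isolated))
    writeLines(paste("# node", isolated), con)
  if (nrow(net$edges))
    writeLines(paste(net$edges[, 1L], net$edges[, 2L], sep = "\t"), con)
  invisible(path)
}

# read_edge_list skips comments, so recover isolated nodes too.
#' Read an edge list together with its `# node` comment lines
#' @inheritParams read_edge_list
#' @return A [ppi_network()] including isolated nodes.
#' @export
read_edge_list_full <- function(path) {
  net <- read_edge_list(path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  iso <- sub("^#[ ]*node[ ]+", "", grep("^#[ ]*node[ ]+", lines, value = TRUE))
  ppi_network(net$edges, nodes = c(net$nodes, iso))
}

#' Minimal PSI-MITAB 2.5 reader
#'
#' Only columns 1-2 (interactor identifiers as pipe-joined `db:accession`
#' entries) are consumed; the first parseable identifier per column is used.
#' Header lines beginning with `#` are skipped; a row whose identifiers
#' cannot be parsed is skipped with a warning.  Deduplication is undirected,
#' as in [read_edge_list()].
#'
#' @param path Path to a MITAB file.
#' @return A [ppi_network()].
#' @export
read_mitab_min <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L) return(ppi_network(matrix(character(), ncol = 2)))
  first_id <- function(cell) {
    for (tok in strsplit(cell, "|", fixed = TRUE)[[1]]) {
      m <- regmatches(tok, regexec("^[^:]+:\"?([^\"(]+)\"?", tok))[[1]]
      if (length(m) == 2L && nzchar(trimws(m[[2L]]))) return(trimws(m[[2L]]))
    }
    NA_character_
  }
  edges <- matrix(character(), ncol = 2L)
  skipped <- 0L
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L)
      stop("MITAB format error at row ", i, ": fewer than 2 columns")
    a <- first_id(f[[1L]]); b <- first_id(f[[2L]])
    if (is.na(a) || is.na(b)) { skipped <- skipped + 1L; next }
    edges <- rbind(edges, c(a, b))
  }
  if (skipped > 0L)
    warning(skipped, " MITAB row(s) skipped: no parseable identifier")
  ppi_network(edges)
}

#' Read a one-column universe gene list
#'
#' @param path TSV with one gene identifier per line; `#` comment lines and
#'   an optional `gene`/`id` header are skipped.
#' @return Character vector of unique gene identifiers (non-empty).
#' @export
read_universe_tsv <- function(path) {
  lines <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) && tolower(lines[[1L]]) %in% c("gene", "gene_id", "id"))
    lines <- lines[-1L]
  genes <- unique(lines)
  if (length(genes) == 0L) stop("universe list is empty")
  genes
}

#' Parse a numeric cell in either decimal dialect
#'
#' Published enrichment tables from European groups print decimal commas
#' (`"102,352"`, `"3,62292E-10"`); result files written by this package use
#' decimal points.  Accepts integer, decimal-comma, decimal-point and
#' scientific forms; thousands separators are not supported.
#'
#' @param text Character vector of numeric cell strings.
#' @return Numeric vector of the exact parsed values.
#' @examples
#' parse_decimal(c("102,352", "3,62292E-10", "0.05"))
#' @export
parse_decimal <- function(text) {
  text <- trimws(as.character(text))
  ok <- grepl("^[+-]?[0-9]+([.,][0-9]+)?([eE][+-]?[0-9]+)?$", text)
  if (any(!ok))
    stop("non-numeric cell(s): ",
         paste(sQuote(text[!ok][seq_len(min(3, sum(!ok)))]), collapse = ", "))
  as.numeric(gsub(",", ".", text, fixed = TRUE))
}

.is_decimal <- function(text) {
  grepl("^[+-]?[0-9]+([.,][0-9]+)?([eE][+-]?[0-9]+)?$", trimws(text))
}

#' Write an enrichment result table as TSV
#'
#' Numeric columns are written with decimal points at full stored precision,
#' so `read_enrichment_tsv(write_enrichment_tsv(x))` reproduces the values
#' exactly; whole-number probabilities are written `"1.0"`, never blank.
#' List columns (e.g. member gene hits) are comma-joined.
#'
#' @param rows Data frame of result rows (may have zero rows).
#' @param path Output path.
#' @export
write_enrichment_tsv <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  out <- rows
  for (cn in names(out)) {
    col <- out[[cn]]
    if (is.list(col)) {
      out[[cn]] <- vapply(col, function(v) paste(v, collapse = ","),
                          character(1))
    } else if (is.double(col)) {
      out[[cn]] <- fmt_number(col)
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an enrichment result table
#'
#' Columns whose cells all parse as numbers (in either decimal dialect) are
#' converted with [parse_decimal()]; everything else stays character.
#'
#' @param path Path to a TSV result table.
#' @return Data frame.
#' @export
read_enrichment_tsv <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", quote = "",
                          fileEncoding = "UTF-8", check.names = TRUE,
                          stringsAsFactors = FALSE)
  for (cn in names(df)) {
    cells <- df[[cn]]
    if (nrow(df) > 0L && all(.is_decimal(cells))) {
      df[[cn]] <- parse_decimal(cells)
    }
  }
  df
}
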