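# Interactor catalog: data model and counting operations for two-configuration
# yeast two-hybrid hit lists with BiFC localization calls.

# Fixed compartment vocabulary, in canonical order.
.compartments <- c("nuclear", "cytoplasmic", "vesicular")

#' Construct a BiFC localization call
#'
#' A localization call is one of three mutually exclusive variants: a
#' `"pattern"` naming the non-empty set of compartments where fluorescence
#' complementation was seen, `"no_signal"` (no fluorescence in a tested
#' interaction), or `"not_determined"` (interaction not assayed or assay
#' inconclusive).
#'
#' @param status One of `"pattern"`, `"no_signal"`, `"not_determined"`.
#' @param compartments For `"pattern"`, a non-empty subset of
#'   `"nuclear"`, `"cytoplasmic"`, `"vesicular"`.
#' @return An object of class `localization_call`.
#' @export
localization_call <- function(status = c("pattern", "no_signal", "not_determined"),
                              compartments = character()) {
  status <- match.arg(status)
  if (status == "pattern") {
    if (length(compartments) == 0L)
      stop("a localization pattern needs at least one compartment")
    bad <- setdiff(compartments, .compartments)
    if (length(bad))
      stop("unknown compartment(s): ", paste(sQuote(bad), collapse = ", "))
    compartments <- .compartments[.compartments %in% compartments]
  } else {
    compartments <- character()
  }
  structure(list(status = status, compartments = compartments),
            class = "localization_call")
}

#' @export
format.localization_call <- function(x, ...) {
  switch(x$status,
         pattern = paste(x$compartments, collapse = "+"),
         no_signal = "no signal",
         not_determined = "n.d.")
}

#' @export
print.localization_call <- function(x, ...) {
  cat("<localization_call>", format(x), "\n")
  invisible(x)
}

loc_equal <- function(a, b) {
  a$status == b$status && identical(a$compartments, b$compartments)
}

#' Parse a raw BiFC-signal cell into a localization call
#'
#' Cell strings follow the conventions of printed screen tables: `/` means a
#' tested interaction gave no fluorescence, `n.d.` means not determined, and
#' anything else is a compartment list.  Tokenization is case-insensitive,
#' treats commas and the word "and" identically, and ignores repeated tokens,
#' so `"Nuclear, and vesicular"` and `"Nuclear and vesicular"` parse alike.
#'
#' @param text Raw cell string; must be non-empty after trimming.
#' @return A [localization_call()].
#' @examples
#' parse_localization("Nuclear, and vesicular")
#' parse_localization("/")
#' parse_localization("n.d.")
#' @export
parse_localization <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- trimws(text)
  if (!nzchar(s)) stop("empty BiFC cell string")
  if (s == "/") return(localization_call("no_signal"))
  if (tolower(s) %in% c("n.d.", "n.d", "nd")) {
    return(localization_call("not_determined"))
  }
  toks <- tolower(strsplit(gsub(",", " ", s), "[[:space:]]+")[[1]])
  toks <- toks[nzchar(toks) & toks != "and"]
  unknown <- setdiff(unique(toks), .compartments)
  if (length(unknown)) {
    stop("unrecognized localization token(s): ",
         paste(sQuote(unknown), collapse = ", "))
  }
  localization_call("pattern", unique(toks))
}

#' Reference to a protein by gene identity
#'
#' Gene identity is keyed on the Entrez Gene ID, not the symbol: symbols
#' carry aliases and typographical marks in screen tables.
#'
#' @param symbol Gene symbol (non-empty).
#' @param entrez_id Positive integer Entrez Gene ID.
#' @param uniprot_acc Optional UniProtKB accession.
#' @param name Optional free-text protein name.
#' @return An object of class `protein_ref`.
#' @export
protein_ref <- function(symbol, entrez_id, uniprot_acc = NA_character_,
                        name = NA_character_) {
  stopifnot(is.character(symbol), nzchar(symbol))
  entrez_id <- as.integer(entrez_id)
  stopifnot(!is.na(entrez_id), entrez_id > 0L)
  structure(list(symbol = symbol, entrez_id = entrez_id,
                 uniprot_acc = uniprot_acc, name = name),
            class = "protein_ref")
}

.screen_cols <- c("symbol", "entrez_id", "uniprot_acc", "name",
                  "function_note", "configs", "previously_described",
                  "copurification", "bifc")

#' Read a screen hit table from a TSV fixture
#'
#' The fixture format has one header row and columns `symbol`, `entrez_id`,
#' `uniprot_acc`, `name`, `function_note`, `configs` (semicolon-joined subset
#' of `DB`/`AD`), `previously_described` (0/1), `copurification` (Y/N) and
#' `bifc` (verbatim cell string).  The `symbol` cell may carry a trailing
#' `*` (previously described interactor) and/or `§` (found in both screen
#' configurations) on its first token, and a parenthesized alias after it;
#' the marks and alias are stripped into separate fields.  The `*` mark must
#' agree with the `previously_described` column; the `§` mark is kept as a
#' claim to be validated (not trusted) during [merge_screens()].
#'
#' @param path Path to a UTF-8 TSV file.
#' @return A `screen_hits` data frame, one row per interactor, with a
#'   list-column `bifc` of parsed [localization_call()] objects.
#' @export
read_screen_tsv <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", quote = "",
                          fileEncoding = "UTF-8", check.names = TRUE,
                          stringsAsFactors = FALSE)
  missing <- setdiff(.screen_cols, names(df))
  if (length(missing))
    stop("screen table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  first_tok <- sub("[[:space:]].*$", "", trimws(df$symbol))
  prev_mark <- grepl("*", first_tok, fixed = TRUE)
  overlap_mark <- grepl("\u00a7", first_tok, fixed = TRUE)
  symbol <- gsub("[*\u00a7]", "", first_tok)
  if (any(!nzchar(symbol))) stop("empty protein symbol in ", path)
  entrez <- suppressWarnings(as.integer(df$entrez_id))
  if (any(is.na(entrez) | entrez <= 0L))
    stop("non-positive or unparseable entrez_id in ", path)
  if (anyDuplicated(entrez))
    stop("duplicate entrez_id within one screen list: ",
         paste(unique(entrez[duplicated(entrez)]), collapse = ", "))
  prev_col <- trimws(df$previously_described) %in% c("1", "TRUE", "Y")
  if (any(prev_col != prev_mark))
    stop("previously_described column disagrees with '*' marks for: ",
         paste(symbol[prev_col != prev_mark], collapse = ", "))
  cfg <- strsplit(trimws(df$configs), ";", fixed = TRUE)
  bad_cfg <- setdiff(unique(unlist(cfg)), c("DB", "AD"))
  if (length(bad_cfg))
    stop("unknown screen configuration token(s): ",
         paste(sQuote(bad_cfg), collapse = ", "))
  config_db <- vapply(cfg, function(x) "DB" %in% x, logical(1))
  config_ad <- vapply(cfg, function(x) "AD" %in% x, logical(1))
  if (any(!(config_db | config_ad)))
    stop("record with empty screen-configuration set in ", path)
  cop <- toupper(trimws(df$copurification))
  if (any(!cop %in% c("Y", "N")))
    stop("copurification column must be Y or N")
  out <- data.frame(
    symbol = symbol,
    entrez_id = entrez,
    uniprot_acc = df$uniprot_acc,
    name = df$name,
    function_note = df$function_note,
    config_db = config_db,
    config_ad = config_ad,
    previously_described = prev_mark,
    copurification = ifelse(cop == "Y", "confirmed", "not_confirmed"),
    claimed_overlap = overlap_mark,
    bifc_raw = df$bifc,
    stringsAsFactors = FALSE
  )
  out$bifc <- lapply(df$bifc, parse_localization)
  class(out) <- c("screen_hits", "data.frame")
  out
}

.empty_hits <- function() {
  out <- data.frame(symbol = character(), entrez_id = integer(),
                    uniprot_acc = character(), name = character(),
                    function_note = character(), config_db = logical(),
                    config_ad = logical(), previously_described = logical(),
                    copurification = character(), claimed_overlap = logical(),
                    bifc_raw = character(), stringsAsFactors = FALSE)
  out$bifc <- list()
  class(out) <- c("screen_hits", "data.frame")
  out
}

#' Merge the two screen-configuration hit lists into a catalog
#'
#' Records are unioned by Entrez Gene ID; the configuration sets of shared
#' records are unioned, and validation status, previously-described flag and
#' localization call must agree between the two lists (a conflict is an
#' error).  The both-configurations ("overlap") flag is always derived from
#' the merged configuration set; any `§` marks claimed in the fixtures are
#' validated against it with a warning on mismatch, never trusted over it.
#'
#' @param db_hits `screen_hits` from the DB-bait configuration (bait fused to
#'   the DNA-binding domain, screened against the AD-ORF library).
#' @param ad_hits `screen_hits` from the reverse (AD-bait) configuration;
#'   may be `NULL` or empty.
#' @param bait A [protein_ref()] for the bait protein.  The bait may itself
#'   appear as a record (a homodimer entry).
#' @return An `interactor_catalog`: list with elements `bait` and `records`.
#' @export
merge_screens <- function(db_hits, ad_hits = NULL, bait) {
  stopifnot(inherits(bait, "protein_ref"))
  if (is.null(db_hits)) db_hits <- .empty_hits()
  if (is.null(ad_hits)) ad_hits <- .empty_hits()
  for (h in list(db_hits, ad_hits)) {
    if (anyDuplicated(h$entrez_id))
      stop("duplicate entrez_id within one hit list")
  }
  all <- rbind(db_hits, ad_hits)
  if (nrow(all) == 0L) stop("both hit lists are empty")
  pieces <- split(seq_len(nrow(all)), all$entrez_id)
  rows <- lapply(pieces, function(idx) {
    if (length(idx) == 1L) return(all[idx, , drop = FALSE])
    a <- all[idx[1L], , drop = FALSE]
    b <- all[idx[2L], , drop = FALSE]
    conflicts <- character()
    if (a$symbol != b$symbol) conflicts <- c(conflicts, "symbol")
    if (a$previously_described != b$previously_described)
      conflicts <- c(conflicts, "previously_described")
    if (a$copurification != b$copurification)
      conflicts <- c(conflicts, "copurification")
    if (!loc_equal(a$bifc[[1L]], b$bifc[[1L]]))
      conflicts <- c(conflicts, "bifc")
    if (length(conflicts))
      stop("merge conflict for entrez_id ", a$entrez_id, " (", a$symbol,
           "): field(s) ", paste(conflicts, collapse = ", "), " disagree")
    a$config_db <- a$config_db || b$config_db
    a$config_ad <- a$config_ad || b$config_ad
    a$claimed_overlap <- a$claimed_overlap || b$claimed_overlap
    a
  })
  rec <- do.call(rbind, rows)
  rec <- rec[order(rec$symbol, rec$entrez_id), , drop = FALSE]
  rownames(rec) <- NULL
  derived <- rec$config_db & rec$config_ad
  # the marks are a claim carried by fixture files; hit lists assembled in
  # code carry no claim, so only validate when at least one mark was set
  bad <- if (any(rec$claimed_overlap)) which(rec$claimed_overlap != derived)
         else integer()
  if (length(bad))
    warning("'\u00a7' overlap marks disagree with derived configuration sets ",
            "for: ", paste(rec$symbol[bad], collapse = ", "),
            " (derived flag is authoritative)")
  class(rec) <- c("screen_hits", "data.frame")
  structure(list(bait = bait, records = rec), class = "interactor_catalog")
}

#' @export
print.interactor_catalog <- function(x, ...) {
  cat("<interactor_catalog> bait:", x$bait$symbol,
      sprintf("(Entrez %d)", x$bait$entrez_id), "\n")
  cat("  records:", nrow(x$records),
      "| both configurations:", sum(x$records$config_db & x$records$config_ad),
      "\n")
  invisible(x)
}

.drop_bait <- function(catalog, include_bait_self) {
  rec <- catalog$records
  if (!include_bait_self) {
    rec <- rec[rec$entrez_id != catalog$bait$entrez_id, , drop = FALSE]
  }
  rec
}

#' Summary counts over an interactor catalog
#'
#' Published screen reports mix counting conventions: the headline partner
#' count typically excludes the bait homodimer, while validation and BiFC
#' counts include it.  The convention is therefore an explicit argument
#' rather than a hard-coded rule.
#'
#' @param catalog An `interactor_catalog`.
#' @param include_bait_self Keep the bait's homodimer record in the counts?
#' @return One-row data frame with `n_partners`, `n_overlap` (both
#'   configurations), `n_confirmed` (co-purification confirmed) and
#'   `n_bifc_positive` (localization call is a pattern, i.e. neither
#'   no-signal nor not-determined).
#' @export
summarize_counts <- function(catalog, include_bait_self = FALSE) {
  stopifnot(inherits(catalog, "interactor_catalog"))
  if (nrow(catalog$records) == 0L) stop("catalog has no records")
  rec <- .drop_bait(catalog, include_bait_self)
  status <- vapply(rec$bifc, function(b) b$status, character(1))
  data.frame(
    n_partners = nrow(rec),
    n_overlap = sum(rec$config_db & rec$config_ad),
    n_confirmed = sum(rec$copurification == "confirmed"),
    n_bifc_positive = sum(status == "pattern")
  )
}

#' Tally BiFC localization patterns by compartment
#'
#' For each compartment, `n_any` counts records whose pattern contains the
#' compartment and `n_exclusive` counts records whose pattern is exactly that
#' single compartment.  No-signal and not-determined records contribute to
#' neither column.
#'
#' @inheritParams summarize_counts
#' @return Data frame with columns `compartment`, `n_any`, `n_exclusive`.
#' @export
tally_localization <- function(catalog, include_bait_self = FALSE) {
  stopifnot(inherits(catalog, "interactor_catalog"))
  rec <- .drop_bait(catalog, include_bait_self)
  pats <- Filter(function(b) b$status == "pattern", rec$bifc)
  data.frame(
    compartment = .compartments,
    n_any = vapply(.compartments, function(cc) {
      sum(vapply(pats, function(b) cc %in% b$compartments, logical(1)))
    }, integer(1)),
    n_exclusive = vapply(.compartments, function(cc) {
      sum(vapply(pats, function(b) identical(b$compartments, cc), logical(1)))
    }, integer(1)),
    row.names = NULL
  )
}
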