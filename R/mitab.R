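#' Read a PSI-MITAB 2.5 interaction file
#'
#' Parses a tab-delimited PSI-MITAB 2.5 file into one interaction record per
#' row. Column 1 and 2 hold the interactor identifiers, column 7 the
#' interaction detection method(s) as PSI-MI controlled-vocabulary terms,
#' column 13 the source database and columns 10-11 the interactor taxa.
#' Columns beyond the 15 of the 2.5 layout are ignored, as is the confidence
#' column (15): reliability weights are recomputed downstream by
#' [score_interactome()].
#'
#' All `MI:NNNN` accessions found in the method column are collected into a
#' set; free-text method names without an accession are ignored (counted in
#' the `n_no_method` attribute). Rows with fewer than 15 columns are skipped
#' and counted in the `n_skipped` attribute. Comment lines (starting with
#' `#`) and blank lines are ignored silently.
#'
#' @param file Path to a PSI-MITAB 2.5 file.
#' @param strip_db_prefix Drop a leading `db:` database prefix (e.g.
#'   `uniprotkb:P04637` becomes `P04637`) from interactor identifiers.
#'   Default `TRUE`.
#' @param same_taxon_only Drop rows whose two taxon columns are present and
#'   disagree (cross-species records). Off by default; organism selection is
#'   normally handled upstream of the interaction files.
#'
#' @return A tibble with one row per parsed record and columns
#'   `interactor_a`, `interactor_b` (character), `methods` (list of character
#'   vectors of PSI-MI accessions), `source` (character), `taxon_a`,
#'   `taxon_b` (character, `NA` when absent). Attributes `n_skipped` and
#'   `n_no_method` carry the malformed-row and accession-less-method counts.
#' @seealso [filter_experimental()], [map_identifiers()], [write_mitab()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".mitab")
#' writeLines(paste(c("uniprotkb:P1", "uniprotkb:P2", rep("-", 4),
#'   'psi-mi:"MI:0018"(two hybrid)', "-", "-", "taxid:9606", "taxid:9606",
#'   "-", 'psi-mi:"MI:0469"(intact)', "-", "-"), collapse = "\t"), f)
#' read_mitab(f)
read_mitab <- function(file, strip_db_prefix = TRUE, same_taxon_only = FALSE) {
  lines <- tryCatch(readr::read_lines(file),
    error = function(e) stop("cannot read MITAB input '", file, "': ",
                             conditionMessage(e), call. = FALSE))
  parse_mitab_lines(lines, strip_db_prefix = strip_db_prefix,
                    same_taxon_only = same_taxon_only)
}

#' @rdname read_mitab
#' @param lines Character vector of raw MITAB lines (as from [readLines()]).
#' @export
parse_mitab_lines <- function(lines, strip_db_prefix = TRUE,
                              same_taxon_only = FALSE) {
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 15L
  n_skipped <- sum(!ok)
  if (n_skipped > 0L) {
    rlang::warn(paste0("skipped ", n_skipped,
                       " MITAB row(s) with fewer than 15 columns"))
  }
  fields <- fields[ok]

  col <- function(i) vapply(fields, function(x) x[[i]], character(1))
  if (length(fields) == 0L) {
    out <- tibble::tibble(interactor_a = character(), interactor_b = character(),
                          methods = list(), source = character(),
                          taxon_a = character(), taxon_b = character())
    attr(out, "n_skipped") <- n_skipped
    attr(out, "n_no_method") <- 0L
    return(out)
  }

  methods <- stringr::str_extract_all(col(7L), "MI:\\d{4}")
  methods <- lapply(methods, function(m) sort(unique(m)))
  n_no_method <- sum(lengths(methods) == 0L)
  if (n_no_method > 0L) {
    rlang::warn(paste0(n_no_method,
                       " record(s) carry no MI:NNNN accession in the method column"))
  }

  out <- tibble::tibble(
    interactor_a = clean_interactor(col(1L), strip_db_prefix),
    interactor_b = clean_interactor(col(2L), strip_db_prefix),
    methods = methods,
    source = extract_source_label(col(13L)),
    taxon_a = extract_taxid(col(10L)),
    taxon_b = extract_taxid(col(11L))
  )

  if (same_taxon_only) {
    cross <- !is.na(out$taxon_a) & !is.na(out$taxon_b) &
      out$taxon_a != out$taxon_b
    if (any(cross)) {
      rlang::inform(paste0("dropped ", sum(cross), " cross-species record(s)"))
      out <- out[!cross, ]
    }
  }

  attr(out, "n_skipped") <- n_skipped
  attr(out, "n_no_method") <- n_no_method
  out
}

# first pipe-separated token, optionally stripped of its "db:" prefix
clean_interactor <- function(x, strip_db_prefix) {
  x <- sub("\\|.*$", "", x)
  if (strip_db_prefix) x <- sub("^[A-Za-z][A-Za-z0-9_.-]*:", "", x)
  x
}

# `psi-mi:"MI:0469"(intact)` -> "intact"; otherwise the raw token
extract_source_label <- function(x) {
  x <- sub("\\|.*$", "", x)
  par <- stringr::str_match(x, "\\(([^)]*)\\)")[, 2]
  ifelse(is.na(par), x, par)
}

extract_taxid <- function(x) {
  stringr::str_match(x, "taxid:(-?\\d+)")[, 2]
}

#' Keep only experimentally validated interaction records
#'
#' A record is kept if and only if at least one of its detection methods is
#' on the experimental-validation whitelist; kept records have their method
#' set reduced to the whitelisted subset. Records whose method set does not
#' intersect the whitelist (including records with no parsed accession at
#' all) are discarded and counted.
#'
#' @param records Tibble of interaction records, as from [read_mitab()].
#' @param whitelist Character vector of accepted PSI-MI accessions; defaults
#'   to [default_method_whitelist()].
#' @return The kept records, with a `n_discarded` attribute.
#' @export
filter_experimental <- function(records, whitelist = default_method_whitelist()) {
  stopifnot(is.character(whitelist), length(whitelist) > 0L)
  kept_methods <- lapply(records$methods, function(m) m[m %in% whitelist])
  keep <- lengths(kept_methods) > 0L
  out <- records[keep, ]
  out$methods <- kept_methods[keep]
  n_discarded <- sum(!keep)
  rlang::inform(paste0("filter_experimental: kept ", nrow(out), ", discarded ",
                       n_discarded, " record(s)"))
  attr(out, "n_discarded") <- n_discarded
  out
}

#' Map raw interactor identifiers to gene identifiers
#'
#' Translates each record into gene-identifier space through a (possibly
#' one-to-many) identifier map. When an interactor maps to several gene
#' identifiers the record is multiplied: the output contains the full cross
#' product of the two interactors' mappings. Records with an unmappable
#' interactor are dropped and counted in the `n_unmapped` attribute.
#'
#' @param records Tibble of interaction records.
#' @param idmap Tibble with columns `raw_id` and `gene_id`, one row per
#'   mapping (as from [read_id_map()]).
#' @return Records in gene-ID space; one input record with `k_a` and `k_b`
#'   mappings for its interactors yields `k_a * k_b` output records.
#' @export
map_identifiers <- function(records, idmap) {
  stopifnot(all(c("raw_id", "gene_id") %in% names(idmap)))
  lut <- split(idmap$gene_id, idmap$raw_id)
  ga <- lut[records$interactor_a]
  gb <- lut[records$interactor_b]
  mappable <- !vapply(ga, is.null, logical(1)) & !vapply(gb, is.null, logical(1))
  n_unmapped <- sum(!mappable)
  if (n_unmapped > 0L) {
    rlang::inform(paste0("map_identifiers: dropped ", n_unmapped,
                         " record(s) with an unmappable interactor"))
  }
  out <- records[mappable, ]
  out$.ga <- ga[mappable]
  out$.gb <- gb[mappable]
  out <- tidyr::unnest_longer(out, ".ga")
  out <- tidyr::unnest_longer(out, ".gb")
  out$interactor_a <- out$.ga
  out$interactor_b <- out$.gb
  out$.ga <- NULL
  out$.gb <- NULL
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Read a two-column identifier map
#'
#' @param file TSV with header columns `raw_id` and `gene_id`; a raw
#'   identifier may appear on several rows (one-to-many mapping).
#' @return Tibble with columns `raw_id`, `gene_id`.
#' @export
read_id_map <- function(file) {
  readr::read_tsv(file, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)[, c("raw_id", "gene_id")]
}

#' Write interaction records as PSI-MITAB 2.5
#'
#' Serializes records back to the 15-column tab-delimited layout read by
#' [read_mitab()]; unused columns are written as `-`. Parsing the output
#' recovers the retained fields (interactors, method accessions, source
#' label, taxa) exactly.
#'
#' @param records Tibble of interaction records.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_mitab <- function(records, file) {
  method_col <- vapply(records$methods, function(m) {
    if (length(m) == 0L) "-" else paste0('psi-mi:"', m, '"(-)', collapse = "|")
  }, character(1))
  tax <- function(x) ifelse(is.na(x), "-", paste0("taxid:", x))
  rows <- paste(
    records$interactor_a, records$interactor_b, "-", "-", "-", "-",
    method_col, "-", "-", tax(records$taxon_a), tax(records$taxon_b), "-",
    paste0('psi-mi:"MI:0000"(', records$source, ")"), "-", "-",
    sep = "\t"
  )
  readr::write_lines(rows, file)
  invisible(file)
}

#' Default experimental-validation method whitelist
#'
#' PSI-MI interaction-detection methods treated as reliable experimental
#' validation: the two-hybrid family, coimmunoprecipitation variants,
#' affinity chromatography and tandem affinity purification, pull down,
#' cross-linking, X-ray crystallography, NMR, FRET and surface plasmon
#' resonance. This default covers the common experimental families; it is a
#' documented stand-in, and any project with its own curated list should
#' override it (see [read_method_whitelist()]).
#'
#' @return Named character vector of PSI-MI accessions (names are
#'   human-readable method labels).
#' @export
default_method_whitelist <- function() {
  c(
    "two hybrid"                          = "MI:0018",
    "two hybrid array"                    = "MI:0397",
    "two hybrid pooling approach"         = "MI:0398",
    "two hybrid fragment pooling"         = "MI:0399",
    "two hybrid prey pooling"             = "MI:1112",
    "two hybrid bait and prey pooling"    = "MI:1113",
    "anti bait coimmunoprecipitation"     = "MI:0006",
    "anti tag coimmunoprecipitation"      = "MI:0007",
    "coimmunoprecipitation"               = "MI:0019",
    "affinity chromatography technology"  = "MI:0004",
    "tandem affinity purification"        = "MI:0676",
    "pull down"                           = "MI:0096",
    "cross-linking study"                 = "MI:0030",
    "x-ray crystallography"               = "MI:0114",
    "nuclear magnetic resonance"          = "MI:0077",
    "fluorescence resonance energy transfer" = "MI:0055",
    "surface plasmon resonance"           = "MI:0107"
  )
}

#' Read a method whitelist from a config file
#'
#' Accepts either a YAML file (a plain list of accessions, or a mapping with
#' an `accepted` key) or a TSV whose first column holds the accessions.
#'
#' @param file Path to the config file.
#' @return Character vector of PSI-MI accessions.
#' @export
read_method_whitelist <- function(file) {
  wl <- if (grepl("\\.ya?ml$", file)) {
    y <- yaml::read_yaml(file)
    if (is.list(y) && !is.null(y$accepted)) unlist(y$accepted) else unlist(y)
  } else {
    readr::read_tsv(file, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)[[1]]
  }
  wl <- as.character(wl)
  if (length(wl) == 0L) stop("method whitelist is empty", call. = FALSE)
  bad <- !grepl("^MI:\\d{4}$", wl)
  if (any(bad)) {
    stop("whitelist entries are not MI:NNNN accessions: ",
         paste(wl[bad], collapse = ", "), call. = FALSE)
  }
  wl
}
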