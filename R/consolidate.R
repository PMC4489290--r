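#' Consolidate gene-mapped records into a non-redundant interactome
#'
#' Merges validated, gene-mapped interaction records from one or more sources
#' into a single undirected interactome. Each unordered gene pair is stored
#' once, under canonical ordering (lexicographically smaller identifier
#' first); its evidence is the union of the detection-method accessions and
#' of the source-database labels over all contributing records, so a PSI-MI
#' accession appears at most once per interaction. The result is independent
#' of the order of sources and of duplicate records.
#'
#' Self-interactions (a gene with itself) are retained as edges; they count
#' toward the interaction total but are excluded from clustering-coefficient
#' computation (see [network_stats()]).
#'
#' @param ... Tibbles of gene-mapped interaction records (one per source, or
#'   already concatenated), or a single list of such tibbles. If a tibble
#'   lacks a `source` column the name of the argument is used as the source
#'   label.
#' @return An interactome: a tibble of class `ppi_interactome` with columns
#'   `gene_a`, `gene_b` (canonical order), `methods` (list of character),
#'   `sources` (list of character) and `weight` (numeric, `NA` until scored),
#'   sorted by gene pair.
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   interactor_a = c("G2", "G1"), interactor_b = c("G1", "G2"),
#'   methods = list("MI:0006", c("MI:0007", "MI:0006")),
#'   source = c("db1", "db2"))
#' build_interactome(recs)
build_interactome <- function(...) {
  sets <- rlang::list2(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !is.data.frame(sets[[1]])) {
    sets <- sets[[1]]
  }
  labels <- names(sets)
  sets <- purrr::imap(sets, function(s, nm) {
    if (!"source" %in% names(s)) {
      s$source <- if (is.character(nm) && nzchar(nm)) nm else "unknown"
    }
    s[, c("interactor_a", "interactor_b", "methods", "source")]
  })
  recs <- dplyr::bind_rows(sets)
  if (nrow(recs) == 0L) {
    return(new_interactome(tibble::tibble(
      gene_a = character(), gene_b = character(),
      methods = list(), sources = list(), weight = double())))
  }
  out <- recs |>
    dplyr::mutate(
      gene_a = pmin(.data$interactor_a, .data$interactor_b),
      gene_b = pmax(.data$interactor_a, .data$interactor_b)
    ) |>
    dplyr::group_by(.data$gene_a, .data$gene_b) |>
    dplyr::summarise(
      methods = list(sort(unique(unlist(.data$methods)))),
      sources = list(sort(unique(.data$source))),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$gene_a, .data$gene_b) |>
    dplyr::mutate(weight = NA_real_)
  new_interactome(out)
}

new_interactome <- function(x) {
  class(x) <- unique(c("ppi_interactome", class(x)))
  x
}

#' Coerce an edge table to an interactome
#'
#' @param x A data frame with columns `gene_a`, `gene_b`, `methods`,
#'   `sources` and optionally `weight`. Method/source columns may be
#'   pipe-joined strings or list columns.
#' @return A `ppi_interactome` tibble with canonical pair ordering enforced.
#' @export
as_interactome <- function(x) {
  x <- tibble::as_tibble(x)
  if (!is.list(x$methods)) x$methods <- strsplit(x$methods, "|", fixed = TRUE)
  if (!is.list(x$sources)) x$sources <- strsplit(x$sources, "|", fixed = TRUE)
  if (!"weight" %in% names(x)) x$weight <- NA_real_
  a <- pmin(x$gene_a, x$gene_b)
  b <- pmax(x$gene_a, x$gene_b)
  x$gene_a <- a
  x$gene_b <- b
  new_interactome(dplyr::arrange(x, .data$gene_a, .data$gene_b))
}

#' Write / read an interactome edge list as TSV
#'
#' The edge-list format is a plain TSV with columns `gene_a`, `gene_b`,
#' `methods` (pipe-joined PSI-MI accessions), `sources` (pipe-joined database
#' labels) and `weight` (empty until scored). Lines starting with `#` are
#' provenance comments and are skipped on read. The format is directly
#' loadable into network tools such as Cytoscape.
#'
#' @param net An interactome tibble.
#' @param file Output (or input) path.
#' @param id_map Optional tibble (`gene_id`, `symbol`) used to translate the
#'   edge list into a secondary identifier space (e.g. HGNC symbols) before
#'   writing; pairs are re-canonicalized after translation. Genes missing
#'   from the map keep their primary identifier.
#' @param comment Optional character vector written as leading `# ` comment
#'   lines (e.g. a config hash).
#' @return `file` invisibly for the writer; an interactome for the reader.
#' @export
write_interactome <- function(net, file, id_map = NULL, comment = NULL) {
  x <- tibble::as_tibble(net)
  if (!is.null(id_map)) {
    stopifnot(all(c("gene_id", "symbol") %in% names(id_map)))
    lut <- stats::setNames(id_map$symbol, id_map$gene_id)
    tr <- function(g) ifelse(g %in% names(lut), unname(lut[g]), g)
    a <- tr(x$gene_a)
    b <- tr(x$gene_b)
    x$gene_a <- pmin(a, b)
    x$gene_b <- pmax(a, b)
  }
  flat <- tibble::tibble(
    gene_a = x$gene_a,
    gene_b = x$gene_b,
    methods = vapply(x$methods, paste, character(1), collapse = "|"),
    sources = vapply(x$sources, paste, character(1), collapse = "|"),
    weight = x$weight
  )
  con <- file(file, open = "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(names(flat), collapse = "\t"), con)
  if (nrow(flat) > 0L) {
    wt <- ifelse(is.na(flat$weight), "",
                 formatC(flat$weight, digits = 15, format = "g"))
    writeLines(paste(flat$gene_a, flat$gene_b, flat$methods, flat$sources, wt,
                     sep = "\t"), con)
  }
  invisible(file)
}

#' @rdname write_interactome
#' @export
read_interactome <- function(file) {
  x <- readr::read_tsv(file, comment = "#",
                       col_types = readr::cols(
                         gene_a = readr::col_character(),
                         gene_b = readr::col_character(),
                         methods = readr::col_character(),
                         sources = readr::col_character(),
                         weight = readr::col_double()),
                       progress = FALSE)
  as_interactome(x)
}
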