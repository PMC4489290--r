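#' Load Gene Ontology annotations from a local table
#'
#' Reads gene-to-GO-term annotations from either a 4-column TSV (header
#' `gene`, `term`, `evidence`, `aspect`) or a GAF 2.x file (gene from column
#' 2 or 3, term from column 5, evidence from column 7, aspect from column 9).
#' Duplicate rows are collapsed; term sizes (number of distinct annotated
#' genes) are computed from the table. Evidence codes outside the GO
#' controlled vocabulary pass through with a warning.
#'
#' @param file Annotation file path. GAF is detected by a `!gaf-version`
#'   header or the `.gaf` extension, otherwise the TSV layout is assumed.
#' @param descriptions Optional tibble (`term`, `description`) or path to a
#'   2-column TSV with these headers; supplies the term descriptions used by
#'   [extract_keywords()].
#' @param gaf_gene_column For GAF input, which column identifies the gene:
#'   2 (DB object ID, default) or 3 (DB object symbol).
#' @return An object of class `go_annotations`: a list with `gene_terms`
#'   (tibble `gene`, `term`, `evidence`) and `term_info` (tibble `term`,
#'   `description`, `n_genes`).
#' @export
read_annotations <- function(file, descriptions = NULL, gaf_gene_column = 2) {
  first <- readr::read_lines(file, n_max = 1L)
  is_gaf <- grepl("\\.gaf(\\.gz)?$", file) ||
    (length(first) == 1L && grepl("^!", first))
  if (is_gaf) {
    raw <- readr::read_tsv(file, comment = "!", col_names = FALSE,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    stopifnot(ncol(raw) >= 9L)
    gt <- tibble::tibble(gene = raw[[gaf_gene_column]], term = raw[[5L]],
                         evidence = raw[[7L]], aspect = raw[[9L]])
  } else {
    gt <- readr::read_tsv(file, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
    stopifnot(all(c("gene", "term", "evidence") %in% names(gt)))
  }
  desc <- NULL
  if (!is.null(descriptions)) {
    desc <- if (is.character(descriptions)) {
      readr::read_tsv(descriptions,
                      col_types = readr::cols(.default = readr::col_character()),
                      progress = FALSE)
    } else {
      tibble::as_tibble(descriptions)
    }
    stopifnot(all(c("term", "description") %in% names(desc)))
  }
  annotation_set(gt, descriptions = desc)
}

# GO evidence codes (GO Consortium controlled vocabulary)
go_evidence_codes <- c(
  "EXP", "IDA", "IPI", "IMP", "IGI", "IEP",
  "HTP", "HDA", "HMP", "HGI", "HEP",
  "IBA", "IBD", "IKR", "IRD",
  "ISS", "ISO", "ISA", "ISM", "IGC", "RCA",
  "TAS", "NAS", "IC", "ND", "IEA"
)

#' Construct an annotation set from in-memory tables
#'
#' @param gene_terms Tibble with columns `gene`, `term`, `evidence` (an
#'   `aspect` column is accepted and ignored beyond storage).
#' @param descriptions Optional tibble (`term`, `description`).
#' @return A `go_annotations` object; term sizes are the number of distinct
#'   genes carrying each term.
#' @export
annotation_set <- function(gene_terms, descriptions = NULL) {
  gt <- tibble::as_tibble(gene_terms)
  gt <- dplyr::distinct(gt, .data$gene, .data$term, .data$evidence)
  unknown <- setdiff(unique(gt$evidence), go_evidence_codes)
  if (length(unknown) > 0L) {
    rlang::warn(paste0("unknown GO evidence code(s): ",
                       paste(unknown, collapse = ", ")))
  }
  sizes <- gt |>
    dplyr::distinct(.data$gene, .data$term) |>
    dplyr::count(.data$term, name = "n_genes")
  term_info <- sizes
  term_info$description <- NA_character_
  if (!is.null(descriptions)) {
    term_info <- dplyr::left_join(sizes, tibble::as_tibble(descriptions),
                                  by = "term")
    extra <- dplyr::anti_join(tibble::as_tibble(descriptions), sizes, by = "term")
    if (nrow(extra) > 0L) {
      extra$n_genes <- 0L
      term_info <- dplyr::bind_rows(term_info, extra[, names(term_info)])
    }
  }
  structure(list(gene_terms = gt,
                 term_info = term_info[, c("term", "description", "n_genes")]),
            class = "go_annotations")
}

#' @export
print.go_annotations <- function(x, ...) {
  cat("GO annotation set: ", length(unique(x$gene_terms$gene)), " genes, ",
      nrow(x$term_info), " terms, ", nrow(x$gene_terms), " annotations\n",
      sep = "")
  invisible(x)
}

#' Genes annotated to a selection of GO terms
#'
#' Returns the genes carrying at least one annotation whose term is in the
#' effective selection and whose evidence code is allowed. The effective
#' selection excludes any term annotated to more genes than `max_term_size`
#' (a guard against overly broad terms); when `allowed_evidence` is `NULL`
#' all evidence codes qualify.
#'
#' "Annotated to" means direct annotation by default. When `ancestors` is
#' supplied (a named list mapping each term to its GO-graph ancestor terms),
#' a gene also qualifies if a selected term is an ancestor of one of its
#' direct annotations.
#'
#' @param ann A `go_annotations` object.
#' @param terms Character vector of selected GO term accessions.
#' @param max_term_size Optional integer; terms annotated to more genes are
#'   dropped from the selection.
#' @param allowed_evidence Optional character vector of GO evidence codes.
#' @param ancestors Optional named list for GO-graph propagation (off when
#'   `NULL`, the default).
#' @return Character vector of gene identifiers (sorted, unique).
#' @export
annotated_genes <- function(ann, terms, max_term_size = NULL,
                            allowed_evidence = NULL, ancestors = NULL) {
  stopifnot(inherits(ann, "go_annotations"), length(terms) > 0L)
  if (!is.null(max_term_size)) {
    too_big <- ann$term_info$term[ann$term_info$n_genes > max_term_size]
    terms <- setdiff(terms, too_big)
  }
  gt <- ann$gene_terms
  if (!is.null(allowed_evidence)) gt <- gt[gt$evidence %in% allowed_evidence, ]
  if (!is.null(ancestors)) {
    eff <- lapply(gt$term, function(tm) c(tm, ancestors[[tm]]))
    hit <- vapply(eff, function(tms) any(tms %in% terms), logical(1))
  } else {
    hit <- gt$term %in% terms
  }
  sort(unique(gt$gene[hit]))
}

# stop-words excluded from GO keyword extraction; function words plus the
# generic ontology fillers "process"/"activity"
keyword_stopwords <- c(
  "of", "to", "the", "in", "and", "or", "by", "a", "an", "via", "from",
  "into", "process", "activity"
)

# light affix stripper: one suffix (longest match first) and one prefix,
# each removed only when enough of the word remains
strip_affixes <- function(words) {
  for (suf in c("ation", "ion", "ing", "es", "s")) {
    hit <- endsWith(words, suf) & nchar(words) - nchar(suf) >= 3L
    words[hit] <- substr(words[hit], 1L, nchar(words[hit]) - nchar(suf))
  }
  for (pre in c("de", "re")) {
    hit <- startsWith(words, pre) & nchar(words) - nchar(pre) >= 4L
    words[hit] <- substr(words[hit], nchar(pre) + 1L, nchar(words[hit]))
  }
  words
}

#' Rank keywords across GO term descriptions
#'
#' Tokenizes the term descriptions (lower-cased, split on non-letter
#' characters), removes stop-words, strips a fixed list of English suffixes
#' (-ation, -ion, -ing, -es, -s) and prefixes (de-, re-), and deduplicates
#' tokens within each term. Keywords are ranked by the number of distinct
#' terms whose description contains them, ties broken alphabetically, and
#' the top `k` are returned. This mirrors the keyword shortcuts that GO-term
#' selection interfaces offer.
#'
#' @param ann A `go_annotations` object (with descriptions loaded) or a
#'   tibble with columns `term` and `description`.
#' @param k Number of keywords to return (default 16); `k <= 0` gives an
#'   empty result.
#' @return Tibble with columns `keyword` and `n_terms`, sorted by decreasing
#'   `n_terms` then alphabetically, at most `k` rows.
#' @export
extract_keywords <- function(ann, k = 16) {
  info <- if (inherits(ann, "go_annotations")) ann$term_info else tibble::as_tibble(ann)
  stopifnot(all(c("term", "description") %in% names(info)))
  if (k <= 0) return(tibble::tibble(keyword = character(), n_terms = integer()))
  info <- info[!is.na(info$description), ]
  tokens <- purrr::map2(info$term, tolower(info$description), function(tm, d) {
    w <- unlist(strsplit(d, "[^a-z]+"))
    w <- w[nchar(w) >= 2L & !(w %in% keyword_stopwords)]
    unique(strip_affixes(w))
  })
  counts <- tibble::tibble(keyword = unlist(tokens)) |>
    dplyr::count(.data$keyword, name = "n_terms") |>
    dplyr::arrange(dplyr::desc(.data$n_terms), .data$keyword)
  utils::head(counts, k)
}
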