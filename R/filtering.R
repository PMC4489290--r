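#' Create an expression profile
#'
#' An expression profile is one resource's gene-level measurements plus the
#' thresholds that define "expressed" within that resource. Thresholds apply
#' independently per resource: cross-platform signals are not normalized
#' against each other.
#'
#' @param data Tibble with columns `gene`, `value` and optionally `pvalue`,
#'   or a path to a TSV with these headers.
#' @param threshold Expression-value threshold for this resource.
#' @param resource Resource label (defaults to the file name when `data` is
#'   a path).
#' @param pvalue_threshold Optional p-value cutoff; when set, a gene must
#'   pass both the value and the p-value rule within this resource.
#' @param strict Boundary behavior of the value threshold: `TRUE` (default)
#'   reads "above the threshold" as strictly greater (`>`); `FALSE` uses
#'   `>=`. The p-value rule is `<=` the cutoff (or `<` when `strict_pvalue`).
#' @param strict_pvalue Use `<` instead of `<=` for the p-value cutoff.
#' @return An object of class `ppi_expression_profile`.
#' @export
expression_profile <- function(data, threshold, resource = NULL,
                               pvalue_threshold = NULL, strict = TRUE,
                               strict_pvalue = FALSE) {
  if (is.character(data) && length(data) == 1L) {
    if (is.null(resource)) resource <- basename(data)
    data <- readr::read_tsv(data, col_types = readr::cols(
      gene = readr::col_character(), .default = readr::col_double()),
      progress = FALSE)
  }
  data <- tibble::as_tibble(data)
  stopifnot(all(c("gene", "value") %in% names(data)),
            is.numeric(threshold), length(threshold) == 1L)
  if (is.null(resource)) resource <- "expression"
  structure(list(resource = resource, data = data, threshold = threshold,
                 pvalue_threshold = pvalue_threshold, strict = strict,
                 strict_pvalue = strict_pvalue),
            class = "ppi_expression_profile")
}

#' @export
print.ppi_expression_profile <- function(x, ...) {
  cat("Expression profile '", x$resource, "': ", nrow(x$data),
      " gene(s), value threshold ", ifelse(x$strict, "> ", ">= "),
      x$threshold, sep = "")
  if (!is.null(x$pvalue_threshold)) {
    cat(", p-value ", ifelse(x$strict_pvalue, "< ", "<= "),
        x$pvalue_threshold, sep = "")
  }
  cat("\n")
  invisible(x)
}

# genes passing one profile's own thresholds
profile_expressed <- function(p) {
  d <- p$data
  pass <- if (p$strict) d$value > p$threshold else d$value >= p$threshold
  if (!is.null(p$pvalue_threshold)) {
    stopifnot("pvalue" %in% names(d))
    pv <- if (p$strict_pvalue) d$pvalue < p$pvalue_threshold
          else d$pvalue <= p$pvalue_threshold
    pass <- pass & pv
  }
  pass[is.na(pass)] <- FALSE
  unique(d$gene[pass])
}

#' Genes considered expressed across expression resources
#'
#' A gene is expressed when it passes its resource's own thresholds in at
#' least one of the selected profiles (OR semantics; a gene absent from a
#' profile is simply not expressed by that profile — values are never
#' imputed). Set `combine = "all"` to require every profile instead, for
#' stringent analyses.
#'
#' @param profiles A `ppi_expression_profile` or a list of them.
#' @param combine `"any"` (default) or `"all"`.
#' @return Sorted character vector of expressed gene identifiers.
#' @export
expressed_genes <- function(profiles, combine = c("any", "all")) {
  combine <- match.arg(combine)
  if (inherits(profiles, "ppi_expression_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) > 0L)
  sets <- lapply(profiles, profile_expressed)
  out <- if (combine == "any") {
    unique(unlist(sets))
  } else {
    Reduce(intersect, sets)
  }
  sort(out)
}

#' Filter an interactome by expression context
#'
#' An interaction cannot occur if either pair-mate is absent, so an edge is
#' kept only when both its genes are expressed under the selected profiles.
#' Weights and evidence are carried through unchanged.
#'
#' @param net An interactome tibble.
#' @inheritParams expressed_genes
#' @return The filtered interactome (a subset of `net`'s rows).
#' @export
filter_by_expression <- function(net, profiles, combine = c("any", "all")) {
  genes <- expressed_genes(profiles, combine = combine)
  keep_nodes(net, genes)
}

#' Filter an interactome by GO annotation
#'
#' Keeps only interactions where both pair-mates carry at least one direct
#' annotation to a term in the input list — e.g. mitochondrial
#' cellular-component terms to focus on interactions occurring in the
#' mitochondria.
#'
#' @param net An interactome tibble.
#' @param ann A `go_annotations` object.
#' @param terms Non-empty character vector of GO term accessions.
#' @inheritParams annotated_genes
#' @return The filtered interactome.
#' @export
filter_by_go <- function(net, ann, terms, max_term_size = NULL,
                         allowed_evidence = NULL, ancestors = NULL) {
  stopifnot(length(terms) > 0L)
  genes <- annotated_genes(ann, terms, max_term_size = max_term_size,
                           allowed_evidence = allowed_evidence,
                           ancestors = ancestors)
  keep_nodes(net, genes)
}

# both-endpoint node filter shared by the expression and GO filters
keep_nodes <- function(net, genes) {
  keep <- net$gene_a %in% genes & net$gene_b %in% genes
  out <- net[keep, ]
  new_interactome(out)
}
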