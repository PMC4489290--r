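#' Summary measurements of an interactome
#'
#' Computes the standard summary reported for each output network: number of
#' proteins, number of interactions, connected components, average
#' clustering coefficient, the node degree distribution and (for weighted
#' networks) the interaction-weight distribution.
#'
#' Conventions: the local clustering coefficient of node `v` is
#' `2 T(v) / (d(v) (d(v) - 1))` with `T(v)` the number of triangles through
#' `v`; nodes of degree < 2 contribute 0 to the average. Self-interactions
#' count toward `n_ppis` but are excluded from degree and triangle counts
#' (the degree histogram is taken on the loop-free simple graph). An empty
#' interactome yields all-zero statistics, with average clustering 0 by
#' convention.
#'
#' @param net An interactome tibble.
#' @return An object of class `ppi_network_stats`: a list with scalars
#'   `n_proteins`, `n_ppis`, `n_self_loops`, `n_components`,
#'   `avg_clustering`, and tibbles `degree_histogram` (`degree`, `count`)
#'   and `weight_histogram` (`bin_low`, `bin_high`, `count`; all-zero
#'   counts when the network is unweighted).
#' @export
#' @examples
#' tri <- as_interactome(tibble::tibble(
#'   gene_a = c("A", "A", "B"), gene_b = c("B", "C", "C"),
#'   methods = list("MI:0018", "MI:0018", "MI:0018"),
#'   sources = list("db", "db", "db")))
#' network_stats(tri)  # 3 proteins, 3 PPIs, 1 component, clustering 1
network_stats <- function(net) {
  if (nrow(net) == 0L) {
    return(structure(list(
      n_proteins = 0L, n_ppis = 0L, n_self_loops = 0L, n_components = 0L,
      avg_clustering = 0,
      degree_histogram = tibble::tibble(degree = integer(), count = integer()),
      weight_histogram = weight_histogram(net)
    ), class = "ppi_network_stats"))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = net$gene_a, to = net$gene_b), directed = FALSE)
  n_self <- sum(net$gene_a == net$gene_b)
  gs <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  loc <- igraph::transitivity(gs, type = "local", isolates = "zero")
  deg <- igraph::degree(gs)
  dh <- tibble::tibble(degree = as.integer(deg)) |>
    dplyr::count(.data$degree, name = "count") |>
    dplyr::arrange(.data$degree)
  structure(list(
    n_proteins = igraph::vcount(g),
    n_ppis = nrow(net),
    n_self_loops = n_self,
    n_components = igraph::count_components(g),
    avg_clustering = mean(loc),
    degree_histogram = dh,
    weight_histogram = weight_histogram(net)
  ), class = "ppi_network_stats")
}

#' @export
print.ppi_network_stats <- function(x, ...) {
  cat("Network statistics\n",
      "  proteins:            ", x$n_proteins, "\n",
      "  PPIs:                ", x$n_ppis,
      if (x$n_self_loops > 0) paste0(" (", x$n_self_loops, " self)") else "", "\n",
      "  connected components:", x$n_components, "\n",
      "  avg clustering:      ", signif(x$avg_clustering, 4), "\n", sep = " ")
  invisible(x)
}

#' One-row summary of network statistics
#'
#' @param x A `ppi_network_stats` object or an interactome tibble (which is
#'   summarized first).
#' @param ... Unused.
#' @return Tibble with columns `n_proteins`, `n_ppis`, `n_self_loops`,
#'   `n_components`, `avg_clustering`, `mean_weight`.
#' @export
glance.ppi_network_stats <- function(x, ...) {
  tibble::tibble(
    n_proteins = x$n_proteins, n_ppis = x$n_ppis,
    n_self_loops = x$n_self_loops, n_components = x$n_components,
    avg_clustering = x$avg_clustering,
    mean_weight = NA_real_
  )
}

#' @rdname glance.ppi_network_stats
#' @export
glance.ppi_interactome <- function(x, ...) {
  out <- glance(network_stats(x))
  out$mean_weight <- if (all(is.na(x$weight))) NA_real_ else
    mean(x$weight, na.rm = TRUE)
  out
}

#' Tidy an interactome into a plain edge tibble
#'
#' @param x An interactome.
#' @param ... Unused.
#' @return A plain tibble with `gene_a`, `gene_b`, pipe-joined `methods` and
#'   `sources`, and `weight`.
#' @export
tidy.ppi_interactome <- function(x, ...) {
  tibble::tibble(
    gene_a = x$gene_a, gene_b = x$gene_b,
    methods = vapply(x$methods, paste, character(1), collapse = "|"),
    sources = vapply(x$sources, paste, character(1), collapse = "|"),
    weight = x$weight
  )
}

#' Write network statistics as a two-column TSV
#'
#' @param stats A `ppi_network_stats` object.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_network_stats <- function(stats, file) {
  tbl <- tibble::tibble(
    measure = c("n_proteins", "n_ppis", "n_self_loops", "n_components",
                "avg_clustering"),
    value = c(stats$n_proteins, stats$n_ppis, stats$n_self_loops,
              stats$n_components, stats$avg_clustering)
  )
  readr::write_tsv(tbl, file, progress = FALSE)
  invisible(file)
}
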