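#' Run the full interactome-construction pipeline
#'
#' Chains the stages end to end: parse the PSI-MITAB sources, keep
#' experimentally validated records, map identifiers to gene space,
#' consolidate into the non-redundant generic interactome, score it with
#' the GO-anchored Bayesian scheme (when scoring is configured), filter it
#' by expression and/or GO context, and compute network statistics for
#' both networks. Edge lists, statistics and per-stage record counts are
#' written to `out_dir`; when a secondary identifier map is supplied each
#' edge list is written twice, once in primary gene identifiers and once in
#' the secondary (e.g. HGNC symbol) space. The pipeline contains no
#' randomness: re-running with identical inputs and config yields
#' byte-identical outputs.
#'
#' @param config A run configuration list (see [read_run_config()] for the
#'   YAML form). Recognized fields:
#' \describe{
#'   \item{mitab}{named character vector of MITAB paths; names are source
#'     labels (unnamed entries are labelled by file name).}
#'   \item{whitelist}{character vector of accessions or a config path;
#'     default [default_method_whitelist()].}
#'   \item{id_map}{path or tibble (`raw_id`, `gene_id`); when absent,
#'     interactor identifiers are assumed to be gene identifiers already.}
#'   \item{annotations, descriptions}{annotation table path (TSV/GAF) or a
#'     `go_annotations` object; required when scoring or GO filtering is
#'     requested.}
#'   \item{grouping}{named accession -> label vector or a config path;
#'     default [default_method_grouping()].}
#'   \item{scoring}{list(`terms`, `max_term_size`, `allowed_evidence`,
#'     `pseudocount` = 1, `prior` = 0.5); omit to skip scoring.}
#'   \item{context}{list(`expression` = list of
#'     list(`path`, `threshold`, `pvalue_threshold`, `label`),
#'     `combine` = "any", `go_terms`); omit to skip filtering.}
#'   \item{symbol_map}{path or tibble (`gene_id`, `symbol`) for the
#'     secondary-identifier output files.}
#'   \item{out_dir}{output directory; when `NULL` nothing is written.}
#'   \item{write_plots}{also write degree/weight distribution PNGs
#'     (default `FALSE`).}
#' }
#' @return A list of class `ppi_run`: `generic` and `filtered` interactomes,
#'   `stats_generic`, `stats_filtered`, `method_scores` (or `NULL`),
#'   `counts` (tibble of per-stage record counts) and `files` (paths
#'   written).
#' @export
run_pipeline <- function(config) {
  cfg <- normalize_config(config)
  counts <- list()

  # parse + validate + map, per source
  whitelist <- cfg$whitelist
  n_parsed <- 0L; n_skipped <- 0L; n_discarded <- 0L; n_unmapped <- 0L
  record_sets <- purrr::imap(cfg$mitab, function(path, label) {
    recs <- read_mitab(path)
    n_parsed <<- n_parsed + nrow(recs)
    n_skipped <<- n_skipped + attr(recs, "n_skipped")
    recs$source <- label
    kept <- filter_experimental(recs, whitelist)
    n_discarded <<- n_discarded + attr(kept, "n_discarded")
    if (!is.null(cfg$id_map)) {
      kept <- map_identifiers(kept, cfg$id_map)
      n_unmapped <<- n_unmapped + attr(kept, "n_unmapped")
    }
    kept
  })
  n_mapped <- sum(vapply(record_sets, nrow, integer(1)))
  counts$records_parsed <- n_parsed
  counts$rows_skipped <- n_skipped
  counts$records_discarded_whitelist <- n_discarded
  counts$records_unmapped <- n_unmapped
  counts$records_mapped <- n_mapped

  generic <- build_interactome(record_sets)
  counts$edges_generic <- nrow(generic)

  # scoring
  scores <- NULL
  if (!is.null(cfg$scoring)) {
    if (is.null(cfg$annotations)) {
      stop("scoring requested but no annotation table configured",
           call. = FALSE)
    }
    sc <- cfg$scoring
    generic <- score_interactome(
      generic, cfg$annotations, sc$terms,
      grouping = cfg$grouping,
      pseudocount = sc$pseudocount %||% 1,
      prior = sc$prior %||% 0.5,
      max_term_size = sc$max_term_size,
      allowed_evidence = sc$allowed_evidence)
    scores <- attr(generic, "method_scores")
  }

  # context filtering
  filtered <- generic
  if (!is.null(cfg$context)) {
    ctx <- cfg$context
    if (!is.null(ctx$expression) && length(ctx$expression) > 0) {
      profiles <- purrr::map(ctx$expression, function(e) {
        expression_profile(e$path, threshold = e$threshold,
                           resource = e$label %||% NULL,
                           pvalue_threshold = e$pvalue_threshold)
      })
      filtered <- filter_by_expression(filtered, profiles,
                                       combine = ctx$combine %||% "any")
      counts$edges_after_expression <- nrow(filtered)
    }
    if (!is.null(ctx$go_terms) && length(ctx$go_terms) > 0) {
      if (is.null(cfg$annotations)) {
        stop("GO filtering requested but no annotation table configured",
             call. = FALSE)
      }
      filtered <- filter_by_go(filtered, cfg$annotations, ctx$go_terms)
      counts$edges_after_go <- nrow(filtered)
    }
  }
  counts$edges_filtered <- nrow(filtered)

  stats_generic <- network_stats(generic)
  stats_filtered <- network_stats(filtered)
  counts_tbl <- tibble::tibble(stage = names(counts),
                               count = unlist(counts, use.names = FALSE))

  files <- character()
  if (!is.null(cfg$out_dir)) {
    files <- write_run_outputs(cfg, generic, filtered, stats_generic,
                               stats_filtered, counts_tbl)
  }

  structure(list(generic = generic, filtered = filtered,
                 stats_generic = stats_generic,
                 stats_filtered = stats_filtered,
                 method_scores = scores, counts = counts_tbl,
                 files = files),
            class = "ppi_run")
}

#' @export
print.ppi_run <- function(x, ...) {
  cat("Interactome pipeline run\n")
  cat("  generic:  ", x$stats_generic$n_proteins, " proteins, ",
      x$stats_generic$n_ppis, " PPIs\n", sep = "")
  cat("  filtered: ", x$stats_filtered$n_proteins, " proteins, ",
      x$stats_filtered$n_ppis, " PPIs\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

normalize_config <- function(config) {
  cfg <- config
  stopifnot(!is.null(cfg$mitab), length(cfg$mitab) > 0)
  cfg$mitab <- unlist(cfg$mitab)
  if (is.null(names(cfg$mitab)) || any(!nzchar(names(cfg$mitab)))) {
    nm <- names(cfg$mitab) %||% rep("", length(cfg$mitab))
    nm[!nzchar(nm)] <- tools::file_path_sans_ext(basename(cfg$mitab[!nzchar(nm)]))
    names(cfg$mitab) <- nm
  }
  missing <- cfg$mitab[!file.exists(cfg$mitab)]
  if (length(missing) > 0) {
    stop("MITAB input file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cfg$whitelist <- if (is.null(cfg$whitelist)) default_method_whitelist()
    else if (is.character(cfg$whitelist) && length(cfg$whitelist) == 1 &&
             file.exists(cfg$whitelist)) read_method_whitelist(cfg$whitelist)
    else cfg$whitelist
  cfg$grouping <- if (is.null(cfg$grouping)) default_method_grouping()
    else if (is.character(cfg$grouping) && length(cfg$grouping) == 1 &&
             is.null(names(cfg$grouping)) && file.exists(cfg$grouping))
      read_method_grouping(cfg$grouping)
    else cfg$grouping
  if (!is.null(cfg$id_map) && is.character(cfg$id_map)) {
    if (!file.exists(cfg$id_map)) stop("id_map file not found: ", cfg$id_map,
                                       call. = FALSE)
    cfg$id_map <- read_id_map(cfg$id_map)
  }
  if (!is.null(cfg$annotations) && !inherits(cfg$annotations, "go_annotations")) {
    if (!file.exists(cfg$annotations)) stop("annotation file not found: ",
                                            cfg$annotations, call. = FALSE)
    cfg$annotations <- read_annotations(cfg$annotations,
                                        descriptions = cfg$descriptions)
  }
  if (!is.null(cfg$symbol_map) && is.character(cfg$symbol_map)) {
    cfg$symbol_map <- readr::read_tsv(
      cfg$symbol_map,
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE)
  }
  if (!is.null(cfg$scoring)) {
    if (is.null(cfg$scoring$terms) || length(cfg$scoring$terms) == 0) {
      stop("scoring configured without GO terms", call. = FALSE)
    }
    cfg$scoring$terms <- unlist(cfg$scoring$terms)
  }
  if (!is.null(cfg$context) && !is.null(cfg$context$expression)) {
    for (e in cfg$context$expression) {
      if (!file.exists(e$path)) stop("expression file not found: ", e$path,
                                     call. = FALSE)
    }
  }
  cfg
}

write_run_outputs <- function(cfg, generic, filtered, stats_generic,
                              stats_filtered, counts_tbl) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- rlang::hash(cfg[setdiff(names(cfg), "out_dir")])
  hdr <- paste0("config_hash: ", hash)
  p <- function(...) file.path(cfg$out_dir, paste0(...))
  files <- c(generic = p("generic_interactome.tsv"),
             filtered = p("filtered_interactome.tsv"))
  write_interactome(generic, files["generic"], comment = hdr)
  write_interactome(filtered, files["filtered"], comment = hdr)
  if (!is.null(cfg$symbol_map)) {
    files["generic_symbols"] <- p("generic_interactome_symbols.tsv")
    files["filtered_symbols"] <- p("filtered_interactome_symbols.tsv")
    write_interactome(generic, files["generic_symbols"],
                      id_map = cfg$symbol_map, comment = hdr)
    write_interactome(filtered, files["filtered_symbols"],
                      id_map = cfg$symbol_map, comment = hdr)
  }
  files["stats_generic"] <- p("network_stats_generic.tsv")
  files["stats_filtered"] <- p("network_stats_filtered.tsv")
  write_network_stats(stats_generic, files["stats_generic"])
  write_network_stats(stats_filtered, files["stats_filtered"])
  files["counts"] <- p("stage_counts.tsv")
  readr::write_tsv(counts_tbl, files["counts"], progress = FALSE)
  if (isTRUE(cfg$write_plots)) {
    files["degree_plot"] <- p("degree_distribution.png")
    ggplot2::ggsave(files["degree_plot"], plot_degree_distribution(generic),
                    width = 6, height = 4, dpi = 150)
    if (any(!is.na(generic$weight))) {
      files["weight_plot"] <- p("weight_distribution.png")
      ggplot2::ggsave(files["weight_plot"], plot_weight_distribution(generic),
                      width = 6, height = 4, dpi = 150)
    }
  }
  files
}

#' Read a pipeline configuration from YAML
#'
#' Loads a YAML run configuration and resolves every relative path against
#' the YAML file's directory. The YAML mirrors the `config` list of
#' [run_pipeline()]; `mitab` may be a mapping (label -> path) or a list of
#' paths.
#'
#' @param file YAML config path.
#' @return A config list ready for [run_pipeline()].
#' @export
read_run_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  base <- dirname(normalizePath(file))
  resolve <- function(p) {
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  cfg$mitab <- vapply(cfg$mitab, identity, character(1))
  cfg$mitab[] <- resolve(cfg$mitab)
  for (f in c("whitelist", "grouping", "id_map", "annotations",
              "descriptions", "symbol_map")) {
    if (!is.null(cfg[[f]]) && is.character(cfg[[f]]) &&
        length(cfg[[f]]) == 1 && grepl("[/.]", cfg[[f]])) {
      cfg[[f]] <- resolve(cfg[[f]])
    }
  }
  if (!is.null(cfg$context$expression)) {
    cfg$context$expression <- lapply(cfg$context$expression, function(e) {
      e$path <- resolve(e$path)
      e
    })
  }
  if (!is.null(cfg$out_dir)) cfg$out_dir <- resolve(cfg$out_dir)
  cfg
}
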