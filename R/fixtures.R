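#' Specify a synthetic interactome dataset
#'
#' Describes a seeded synthetic dataset in exactly the formats the pipeline
#' reads: per-source PSI-MITAB files, an identifier map, GO annotation and
#' term-description tables, and per-resource expression tables, together
#' with a JSON manifest recording every planted ground truth.
#'
#' The generator plants a two-block structure chosen so every pipeline
#' stage has a known outcome: genes are partitioned into GO modules plus a
#' background set, each gene carrying exactly one direct annotation (its
#' module term, or the shared background term). A neutral detection method
#' (two hybrid, MI:0018) is recorded on every interaction, so its
#' likelihood ratio is close to 1 by construction, while a boosted method
#' (a coimmunoprecipitation variant, MI:0006 or MI:0007) is recorded only
#' on within-module interactions, so its ratio must exceed 1 when the
#' module terms anchor the positive reference set. Planted non-experimental
#' rows, one-to-many and missing identifier mappings, and duplicate pairs
#' across sources exercise the filtering, mapping and consolidation stages.
#'
#' @param n_genes Number of genes (default 60).
#' @param n_edges Number of distinct experimental gene-pair interactions
#'   (default 120).
#' @param n_sources Number of source databases (default 2).
#' @param method_pool Optional extra whitelisted PSI-MI accessions sprinkled
#'   on interactions, with sampling weights.
#' @param pool_prob Probability that an interaction record carries one extra
#'   method from `method_pool` (default 0.3).
#' @param fraction_nonexperimental Non-experimental MITAB rows (method
#'   MI:0063, interaction prediction) planted as a fraction of `n_edges`
#'   (default 0.1).
#' @param go_module_sizes Sizes of the planted GO modules (default two
#'   modules of 12 genes).
#' @param within_module_density Fraction of each module's possible pairs
#'   realized as boosted within-module interactions (default 0.25).
#' @param expression_resources Tibble (or data.frame) with columns `label`,
#'   `fraction_expressed`, `threshold`: one expression table per row.
#' @param n_multi_map One-to-many identifier-map entries (raw IDs mapping to
#'   2 genes each), each used by one planted record (default 2).
#' @param n_unmapped Records whose bait identifier is absent from the map
#'   (default 2).
#' @param n_duplicate_pairs Interactions emitted by two sources (default 8).
#' @param seed Integer seed; identical spec + seed gives byte-identical
#'   output files.
#' @return A `ppi_fixture_spec` list.
#' @seealso [generate_fixture()]
#' @export
fixture_spec <- function(n_genes = 60, n_edges = 120, n_sources = 2,
                         method_pool = c("MI:0096" = 2, "MI:0114" = 1,
                                         "MI:0077" = 1),
                         pool_prob = 0.3,
                         fraction_nonexperimental = 0.1,
                         go_module_sizes = c(12, 12),
                         within_module_density = 0.25,
                         expression_resources = tibble::tibble(
                           label = c("rnaseq", "proteomics"),
                           fraction_expressed = c(0.7, 0.6),
                           threshold = c(1, 1)),
                         n_multi_map = 2, n_unmapped = 2,
                         n_duplicate_pairs = 8, seed = 1L) {
  stopifnot(n_genes >= sum(go_module_sizes) + 2,
            fraction_nonexperimental >= 0, fraction_nonexperimental <= 1,
            n_sources >= 1, seed == as.integer(seed))
  spec <- list(n_genes = n_genes, n_edges = n_edges, n_sources = n_sources,
               method_pool = method_pool, pool_prob = pool_prob,
               fraction_nonexperimental = fraction_nonexperimental,
               go_module_sizes = go_module_sizes,
               within_module_density = within_module_density,
               expression_resources = tibble::as_tibble(expression_resources),
               n_multi_map = n_multi_map, n_unmapped = n_unmapped,
               n_duplicate_pairs = n_duplicate_pairs, seed = as.integer(seed))
  class(spec) <- "ppi_fixture_spec"
  spec
}

# run code under a seed without disturbing the caller's RNG state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# sample k unordered pairs (no self pairs) from `pool` (2-column matrix of
# candidate pairs), without replacement
sample_rows <- function(pool, k) {
  stopifnot(k <= nrow(pool))
  pool[sample.int(nrow(pool), k), , drop = FALSE]
}

all_pairs <- function(genes) {
  if (length(genes) < 2L) return(matrix(character(), ncol = 2))
  t(utils::combn(genes, 2L))
}

#' Generate a synthetic dataset on disk
#'
#' Writes the files described by a [fixture_spec()] into `outdir` and a
#' `manifest.json` recording the planted ground truth: per-stage record
#' counts, the module/background gene sets and terms, the expressed gene
#' sets, and the expected edge counts after consolidation and after each
#' context filter. Running the pipeline on the files must recover every
#' manifest count exactly.
#'
#' @param spec A `ppi_fixture_spec`.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (named file paths) and `manifest`
#'   (the ground-truth list, also written as JSON).
#' @export
generate_fixture <- function(spec = fixture_spec(), outdir) {
  stopifnot(inherits(spec, "ppi_fixture_spec"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory ", outdir,
                                call. = FALSE)
  with_local_seed(spec$seed, generate_fixture_impl(spec, outdir))
}

generate_fixture_impl <- function(spec, outdir) {
  genes <- sprintf("G%04d", seq_len(spec$n_genes))
  raw_of <- stats::setNames(sprintf("P%04d", seq_len(spec$n_genes)), genes)

  # GO modules: each gene gets exactly one annotation, so complementing the
  # selected terms exactly swaps the positive and negative reference sets
  n_mod <- length(spec$go_module_sizes)
  module_terms <- sprintf("GO:%07d", seq_len(n_mod))
  background_term <- "GO:0999999"
  idx <- split(seq_len(sum(spec$go_module_sizes)),
               rep(seq_len(n_mod), spec$go_module_sizes))
  module_genes <- lapply(idx, function(i) genes[i])
  bg_genes <- genes[-seq_len(sum(spec$go_module_sizes))]

  # within-module interactions carry the boosted method
  within <- purrr::map_dfr(seq_len(n_mod), function(m) {
    pool <- all_pairs(module_genes[[m]])
    k <- max(1L, round(spec$within_module_density * nrow(pool)))
    p <- sample_rows(pool, k)
    tibble::tibble(gene_a = p[, 1], gene_b = p[, 2], boosted = TRUE)
  })
  pool <- all_pairs(genes)
  key <- paste(pmin(pool[, 1], pool[, 2]), pmax(pool[, 1], pool[, 2]))
  taken <- paste(pmin(within$gene_a, within$gene_b),
                 pmax(within$gene_a, within$gene_b))
  bgpool <- pool[!(key %in% taken), , drop = FALSE]
  n_bg <- max(0L, spec$n_edges - nrow(within))
  bgp <- sample_rows(bgpool, n_bg)
  edges <- dplyr::bind_rows(
    within,
    tibble::tibble(gene_a = bgp[, 1], gene_b = bgp[, 2], boosted = FALSE))

  # methods: neutral on every record; boosted variant on module records;
  # occasional extra whitelisted method from the pool
  neutral <- "MI:0018"
  boosted_acc <- sample(c("MI:0006", "MI:0007"), nrow(edges), replace = TRUE)
  extra <- ifelse(
    stats::runif(nrow(edges)) < spec$pool_prob & length(spec$method_pool) > 0,
    sample(names(spec$method_pool), nrow(edges), replace = TRUE,
           prob = spec$method_pool),
    NA_character_)
  edges$methods <- purrr::pmap(
    list(edges$boosted, boosted_acc, extra),
    function(b, acc, ex) {
      m <- neutral
      if (b) m <- c(m, acc)
      if (!is.na(ex)) m <- c(m, ex)
      sort(unique(m))
    })
  sources <- paste0("db", seq_len(spec$n_sources))
  edges$source <- sample(sources, nrow(edges), replace = TRUE)

  # duplicates: same pair + methods emitted by a second source
  dup_idx <- sample.int(nrow(edges), min(spec$n_duplicate_pairs, nrow(edges)))
  dups <- edges[dup_idx, ]
  if (spec$n_sources > 1) {
    dups$source <- sources[(match(dups$source, sources) %% spec$n_sources) + 1L]
  }

  # one-to-many map entries: one raw id standing for two genes, used by one
  # record each; its partner is a background gene so no self-loop can arise
  multi <- NULL
  multi_map <- NULL
  if (spec$n_multi_map > 0) {
    multi_raw <- sprintf("PM%02d", seq_len(spec$n_multi_map))
    multi_targets <- lapply(seq_len(spec$n_multi_map), function(i)
      sample(unlist(module_genes), 2L))
    partners <- sample(bg_genes, spec$n_multi_map, replace = TRUE)
    multi_map <- tibble::tibble(
      raw_id = rep(multi_raw, each = 2L),
      gene_id = unlist(multi_targets))
    multi <- tibble::tibble(
      raw_a = multi_raw, raw_b = unname(raw_of[partners]),
      methods = rep(list(neutral), spec$n_multi_map),
      source = sample(sources, spec$n_multi_map, replace = TRUE))
    multi_expanded <- tibble::tibble(
      gene_a = unlist(lapply(multi_targets, identity)),
      gene_b = rep(partners, each = 2L),
      methods = rep(list(neutral), 2L * spec$n_multi_map))
  } else {
    multi_expanded <- tibble::tibble(gene_a = character(),
                                     gene_b = character(), methods = list())
  }

  # records with an unmappable interactor (dropped, counted)
  unmapped <- if (spec$n_unmapped > 0) tibble::tibble(
    raw_a = sprintf("PX%02d", seq_len(spec$n_unmapped)),
    raw_b = unname(raw_of[sample(genes, spec$n_unmapped)]),
    methods = rep(list(neutral), spec$n_unmapped),
    source = sample(sources, spec$n_unmapped, replace = TRUE)) else NULL

  # non-experimental rows: interaction prediction only, never whitelisted
  n_nonexp <- round(spec$fraction_nonexperimental * spec$n_edges)
  nonexp <- if (n_nonexp > 0) {
    p <- sample_rows(pool, n_nonexp)
    tibble::tibble(raw_a = unname(raw_of[p[, 1]]), raw_b = unname(raw_of[p[, 2]]),
                   methods = rep(list("MI:0063"), n_nonexp),
                   source = sample(sources, n_nonexp, replace = TRUE))
  } else NULL

  recs <- dplyr::bind_rows(
    tibble::tibble(raw_a = unname(raw_of[edges$gene_a]),
                   raw_b = unname(raw_of[edges$gene_b]),
                   methods = edges$methods, source = edges$source),
    tibble::tibble(raw_a = unname(raw_of[dups$gene_a]),
                   raw_b = unname(raw_of[dups$gene_b]),
                   methods = dups$methods, source = dups$source),
    if (!is.null(multi)) multi[, c("raw_a", "raw_b", "methods", "source")],
    if (!is.null(unmapped)) unmapped,
    if (!is.null(nonexp)) nonexp
  )

  # write one shuffled MITAB file per source
  paths <- list()
  per_source <- integer(0)
  for (s in sources) {
    rs <- recs[recs$source == s, ]
    rs <- rs[sample.int(nrow(rs)), ]
    f <- file.path(outdir, paste0("ppi_", s, ".mitab"))
    write_mitab(tibble::tibble(interactor_a = rs$raw_a, interactor_b = rs$raw_b,
                               methods = rs$methods, source = rs$source,
                               taxon_a = "9606", taxon_b = "9606"), f)
    paths[[paste0("mitab_", s)]] <- f
    per_source[s] <- nrow(rs)
  }

  # identifier maps
  id_map <- dplyr::bind_rows(
    tibble::tibble(raw_id = unname(raw_of), gene_id = names(raw_of)),
    multi_map)
  paths$id_map <- file.path(outdir, "id_map.tsv")
  readr::write_tsv(id_map, paths$id_map, progress = FALSE)
  symbol_map <- tibble::tibble(gene_id = genes,
                               symbol = sprintf("SYM%04d", seq_along(genes)))
  paths$symbol_map <- file.path(outdir, "symbol_map.tsv")
  readr::write_tsv(symbol_map, paths$symbol_map, progress = FALSE)

  # GO annotations (one per gene) and term descriptions
  ann_tbl <- tibble::tibble(
    gene = c(unlist(module_genes), bg_genes),
    term = c(rep(module_terms, spec$go_module_sizes),
             rep(background_term, length(bg_genes))),
    evidence = "IDA", aspect = "P")
  ann_tbl <- ann_tbl[order(ann_tbl$gene), ]
  paths$annotations <- file.path(outdir, "go_annotations.tsv")
  readr::write_tsv(ann_tbl, paths$annotations, progress = FALSE)
  desc <- tibble::tibble(
    term = c(module_terms, background_term),
    description = c(sprintf("synthetic signaling module %d process",
                            seq_len(n_mod)),
                    "synthetic background cellular process"))
  paths$descriptions <- file.path(outdir, "go_descriptions.tsv")
  readr::write_tsv(desc, paths$descriptions, progress = FALSE)

  # expression tables: expressed genes above threshold, a spread of the
  # rest below it, and the remainder absent from the table
  res <- spec$expression_resources
  expressed_sets <- list()
  for (i in seq_len(nrow(res))) {
    lab <- res$label[i]
    thr <- res$threshold[i]
    n_expr <- round(res$fraction_expressed[i] * length(genes))
    expr_genes <- sort(sample(genes, n_expr))
    rest <- setdiff(genes, expr_genes)
    below <- rest[seq_len(floor(length(rest) / 2))]
    tbl <- dplyr::bind_rows(
      tibble::tibble(gene = expr_genes,
                     value = thr + stats::runif(length(expr_genes), 0.5, 5)),
      tibble::tibble(gene = below,
                     value = stats::runif(length(below), 0, thr * 0.9)))
    tbl <- tbl[order(tbl$gene), ]
    tbl$value <- round(tbl$value, 4)
    f <- file.path(outdir, paste0("expression_", lab, ".tsv"))
    readr::write_tsv(tbl, f, progress = FALSE)
    paths[[paste0("expression_", lab)]] <- f
    expressed_sets[[lab]] <- expr_genes
  }

  # ground truth by direct bookkeeping
  gene_edges <- dplyr::bind_rows(
    edges[, c("gene_a", "gene_b", "methods")],
    dups[, c("gene_a", "gene_b", "methods")],
    multi_expanded)
  canon <- tibble::tibble(a = pmin(gene_edges$gene_a, gene_edges$gene_b),
                          b = pmax(gene_edges$gene_a, gene_edges$gene_b))
  pair_key <- paste(canon$a, canon$b)
  uniq <- !duplicated(pair_key)
  n_generic <- sum(uniq)
  expr_union <- sort(unique(unlist(expressed_sets)))
  both_expr <- canon$a %in% expr_union & canon$b %in% expr_union
  mod_all <- unlist(module_genes)
  both_mod <- canon$a %in% mod_all & canon$b %in% mod_all
  neither_mod <- !(canon$a %in% mod_all) & !(canon$b %in% mod_all)

  manifest <- list(
    seed = spec$seed,
    genes = genes,
    sources = sources,
    records_per_source = as.list(per_source),
    n_records_total = nrow(recs),
    n_nonexperimental = n_nonexp,
    n_records_experimental = nrow(recs) - n_nonexp,
    n_unmapped_records = spec$n_unmapped,
    n_multi_map_records = spec$n_multi_map,
    n_records_mapped = nrow(recs) - n_nonexp - spec$n_unmapped +
      spec$n_multi_map,
    n_duplicate_records = nrow(dups),
    n_edges_generic = n_generic,
    n_within_module_edges = nrow(within),
    module_terms = module_terms,
    background_term = background_term,
    module_genes = module_genes,
    background_genes = bg_genes,
    boosted_group = "coimmunoprecipitation",
    neutral_group = "two hybrid",
    n_edges_positive = sum(both_mod[uniq]),
    n_edges_negative = sum(neither_mod[uniq]),
    expression = lapply(seq_len(nrow(res)), function(i) list(
      label = res$label[i], threshold = res$threshold[i],
      expressed = expressed_sets[[res$label[i]]])),
    expressed_union = expr_union,
    n_edges_after_expression = sum(both_expr[uniq]),
    n_edges_after_go_modules = sum(both_mod[uniq])
  )
  paths$manifest <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(paths = paths, manifest = manifest, spec = spec))
}
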