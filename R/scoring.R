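#' Default PSI-MI detection-method grouping
#'
#' Detection methods that differ only slightly identify too few interactions
#' to be scored on their own, so near-identical PSI-MI terms are combined
#' into one scored method. The default table groups anti-bait (MI:0006) and
#' anti-tag (MI:0007) coimmunoprecipitation with generic
#' coimmunoprecipitation (MI:0019), the two-hybrid variants under one
#' two-hybrid label, and tandem affinity purification with affinity
#' chromatography. Accessions not in the table map to themselves. The table
#' is a documented default; override it via [read_method_grouping()] to
#' match a project-specific grouping.
#'
#' @return Named character vector: names are PSI-MI accessions, values the
#'   combined-method labels.
#' @export
default_method_grouping <- function() {
  c(
    "MI:0006" = "coimmunoprecipitation",
    "MI:0007" = "coimmunoprecipitation",
    "MI:0019" = "coimmunoprecipitation",
    "MI:0018" = "two hybrid",
    "MI:0397" = "two hybrid",
    "MI:0398" = "two hybrid",
    "MI:0399" = "two hybrid",
    "MI:1112" = "two hybrid",
    "MI:1113" = "two hybrid",
    "MI:0004" = "affinity chromatography",
    "MI:0676" = "affinity chromatography"
  )
}

#' Read a method-grouping table
#'
#' @param file 2-column TSV with header `accession`, `group` (one PSI-MI
#'   accession per row), or a YAML mapping accession -> group label.
#' @return Named character vector mapping accession to group label.
#' @export
read_method_grouping <- function(file) {
  if (grepl("\\.ya?ml$", file)) {
    y <- yaml::read_yaml(file)
    out <- unlist(y)
  } else {
    x <- readr::read_tsv(file, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
    stopifnot(all(c("accession", "group") %in% names(x)))
    out <- stats::setNames(x$group, x$accession)
  }
  bad <- !grepl("^MI:\\d{4}$", names(out))
  if (any(bad)) {
    stop("grouping keys are not MI:NNNN accessions: ",
         paste(names(out)[bad], collapse = ", "), call. = FALSE)
  }
  out
}

#' Map method accessions to combined-method labels
#'
#' Applies the grouping lookup to a set of PSI-MI accessions; accessions
#' without a group entry map to themselves. The result is deduplicated, so
#' two variants of the same combined method contribute a single label.
#'
#' @param methods Character vector of PSI-MI accessions.
#' @param grouping Named character vector (accession -> label), as from
#'   [default_method_grouping()].
#' @return Sorted character vector of distinct combined-method labels.
#' @export
group_methods <- function(methods, grouping = default_method_grouping()) {
  if (length(methods) == 0L) return(character())
  labels <- ifelse(methods %in% names(grouping),
                   unname(grouping[methods]), methods)
  sort(unique(labels))
}

#' Build GO-anchored positive and negative reference interaction sets
#'
#' Given a selection of GO terms, the positive reference set contains the
#' interactions whose two pair-mates are both annotated to the selected
#' terms, and the negative set those where neither pair-mate is annotated.
#' Interactions with exactly one annotated pair-mate are "mixed" and belong
#' to neither set: the two definitions do not cover them, and excluding them
#' avoids contaminating either label.
#'
#' @param net An interactome tibble.
#' @param ann A `go_annotations` object.
#' @param terms Character vector of selected GO term accessions.
#' @inheritParams annotated_genes
#' @return A list of class `ppi_reference_sets` with logical vectors
#'   `positive`, `negative`, `mixed` (aligned to the rows of `net`), the
#'   annotated `genes`, and counts `n_positive`, `n_negative`, `n_mixed`.
#' @export
build_reference_sets <- function(net, ann, terms, max_term_size = NULL,
                                 allowed_evidence = NULL, ancestors = NULL) {
  stopifnot(nrow(net) > 0L)
  genes <- annotated_genes(ann, terms, max_term_size = max_term_size,
                           allowed_evidence = allowed_evidence,
                           ancestors = ancestors)
  a_in <- net$gene_a %in% genes
  b_in <- net$gene_b %in% genes
  positive <- a_in & b_in
  negative <- !a_in & !b_in
  if (!any(positive) || !any(negative)) {
    stop("reference sets are degenerate (", sum(positive), " positive, ",
         sum(negative), " negative interactions): broaden or narrow the ",
         "selected GO terms so both sets are non-empty", call. = FALSE)
  }
  structure(list(positive = positive, negative = negative,
                 mixed = !positive & !negative, genes = genes,
                 n_positive = sum(positive), n_negative = sum(negative),
                 n_mixed = sum(!positive & !negative)),
            class = "ppi_reference_sets")
}

#' @export
print.ppi_reference_sets <- function(x, ...) {
  cat("PPI reference sets: ", x$n_positive, " positive, ", x$n_negative,
      " negative, ", x$n_mixed, " mixed interaction(s)\n", sep = "")
  invisible(x)
}

#' Score combined detection methods by likelihood ratio
#'
#' For each combined method `m`, let `TP` be the number of positive-set
#' interactions detected by `m` and `FP` the number of negative-set
#' interactions detected by `m` (detection means presence of the method on
#' the consolidated edge; evidence multiplicity was erased by unification).
#' The likelihood ratio with Laplace pseudocount `alpha` is
#'
#' \deqn{lr(m) = \frac{(TP+\alpha)/(|P|+2\alpha)}{(FP+\alpha)/(|N|+2\alpha)}}
#'
#' A ratio above 1 means the method preferentially detects interactions
#' between proteins sharing the selected GO context. The pseudocount keeps
#' every ratio finite and strictly positive.
#'
#' @param net An interactome tibble.
#' @param refs Reference sets from [build_reference_sets()] built on `net`.
#' @param grouping Method grouping (accession -> label).
#' @param pseudocount Laplace pseudocount `alpha` (> 0, default 1).
#' @param prior Prior probability `pi` that an interaction is true, stored
#'   for downstream weighting (in (0,1), default 0.5).
#' @return A `ppi_method_scores` object: a tibble with columns `group`,
#'   `tp`, `fp`, `lr`, plus attributes `pseudocount`, `prior`, `n_positive`,
#'   `n_negative`.
#' @export
score_methods <- function(net, refs, grouping = default_method_grouping(),
                          pseudocount = 1, prior = 0.5) {
  stopifnot(inherits(refs, "ppi_reference_sets"),
            length(refs$positive) == nrow(net),
            pseudocount > 0, prior > 0, prior < 1)
  edge_groups <- lapply(net$methods, group_methods, grouping = grouping)
  all_groups <- sort(unique(unlist(edge_groups)))
  a <- pseudocount
  n_pos <- refs$n_positive
  n_neg <- refs$n_negative
  tab <- purrr::map_dfr(all_groups, function(g) {
    on_edge <- vapply(edge_groups, function(eg) g %in% eg, logical(1))
    tp <- sum(on_edge & refs$positive)
    fp <- sum(on_edge & refs$negative)
    tibble::tibble(group = g, tp = tp, fp = fp,
                   lr = ((tp + a) / (n_pos + 2 * a)) /
                        ((fp + a) / (n_neg + 2 * a)))
  })
  structure(tab, class = c("ppi_method_scores", class(tab)),
            pseudocount = pseudocount, prior = prior,
            n_positive = n_pos, n_negative = n_neg)
}

#' @export
print.ppi_method_scores <- function(x, ...) {
  cat("Method likelihood ratios (", attr(x, "n_positive"), " positive / ",
      attr(x, "n_negative"), " negative reference PPIs, alpha = ",
      attr(x, "pseudocount"), ", prior = ", attr(x, "prior"), "):\n", sep = "")
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a method-score object
#'
#' @param x A `ppi_method_scores` object.
#' @param ... Unused.
#' @return A plain tibble with one row per combined method: `group`, `tp`,
#'   `fp`, `lr`.
#' @export
tidy.ppi_method_scores <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- setdiff(class(out), "ppi_method_scores")
  out
}

#' One-row summary of a method-score object
#'
#' @param x A `ppi_method_scores` object.
#' @param ... Unused.
#' @return Tibble with `n_methods`, `n_positive`, `n_negative`,
#'   `pseudocount`, `prior`, `max_lr`, `min_lr`.
#' @export
glance.ppi_method_scores <- function(x, ...) {
  tibble::tibble(
    n_methods = nrow(x),
    n_positive = attr(x, "n_positive"),
    n_negative = attr(x, "n_negative"),
    pseudocount = attr(x, "pseudocount"),
    prior = attr(x, "prior"),
    max_lr = max(x$lr),
    min_lr = min(x$lr)
  )
}

#' Posterior weight of one interaction from its combined methods
#'
#' Naive-Bayes combination: the per-method likelihood ratios of the distinct
#' combined methods on the edge are multiplied into a joint ratio `L`, and
#' the posterior weight is `pi * L / (pi * L + (1 - pi))` for prior `pi`
#' (with the default `pi = 0.5`, `L / (L + 1)`). Each combined method
#' contributes exactly once regardless of how many of its PSI-MI variants
#' detected the interaction, so overlapping evidence is ignored. A group
#' never seen during scoring contributes a neutral ratio of 1, with a
#' warning.
#'
#' @param groups Character vector of combined-method labels (non-empty).
#' @param scores A `ppi_method_scores` object.
#' @return Weight in (0, 1).
#' @export
score_interaction <- function(groups, scores) {
  stopifnot(length(groups) > 0L)
  groups <- unique(groups)
  lr <- stats::setNames(scores$lr, scores$group)
  missing <- setdiff(groups, names(lr))
  if (length(missing) > 0L) {
    rlang::warn(paste0("no likelihood ratio for group(s) ",
                       paste(missing, collapse = ", "),
                       "; treating as lr = 1"))
  }
  L <- prod(lr[intersect(groups, names(lr))])
  p <- attr(scores, "prior")
  (p * L) / (p * L + (1 - p))
}

#' Weight every interaction of an interactome
#'
#' Runs the full two-step Bayesian scoring: builds the GO-anchored reference
#' sets, scores the combined detection methods by likelihood ratio, and
#' assigns each interaction its naive-Bayes posterior weight. The weight
#' histogram over 20 equal bins on \[0, 1\] is attached as the
#' `weight_histogram` attribute (see [weight_histogram()]).
#'
#' @inheritParams build_reference_sets
#' @inheritParams score_methods
#' @return The interactome with its `weight` column filled in (all weights
#'   in (0, 1)); attributes `method_scores` (the `ppi_method_scores` object)
#'   and `weight_histogram`.
#' @export
score_interactome <- function(net, ann, terms, grouping = default_method_grouping(),
                              pseudocount = 1, prior = 0.5,
                              max_term_size = NULL, allowed_evidence = NULL,
                              ancestors = NULL) {
  refs <- build_reference_sets(net, ann, terms, max_term_size = max_term_size,
                               allowed_evidence = allowed_evidence,
                               ancestors = ancestors)
  scores <- score_methods(net, refs, grouping = grouping,
                          pseudocount = pseudocount, prior = prior)
  net$weight <- vapply(net$methods, function(m) {
    score_interaction(group_methods(m, grouping), scores)
  }, numeric(1))
  net <- new_interactome(net)
  attr(net, "method_scores") <- scores
  attr(net, "weight_histogram") <- weight_histogram(net)
  net
}

#' Histogram of interaction weights on fixed bins
#'
#' @param net A weighted interactome.
#' @param n_bins Number of equal-width, right-closed bins on \[0, 1\]
#'   (default 20, i.e. breaks 0, 0.05, ..., 1).
#' @return Tibble with columns `bin_low`, `bin_high`, `count`; counts sum to
#'   the number of weighted edges.
#' @export
weight_histogram <- function(net, n_bins = 20) {
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  w <- net$weight[!is.na(net$weight)]
  idx <- findInterval(w, breaks, left.open = TRUE, rightmost.closed = TRUE)
  idx[w <= 0] <- 1L  # weight 0 falls in the first bin
  counts <- tabulate(idx, nbins = n_bins)
  tibble::tibble(bin_low = breaks[-length(breaks)], bin_high = breaks[-1],
                 count = counts)
}
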