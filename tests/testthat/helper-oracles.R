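# Independent brute-force oracles and small random-input builders.
# Everything here is deliberately naive (plain loops over environments /
# matrices) and shares no code with the package implementation.

# --- consolidation oracle: loop over records, keep a dictionary keyed by the
# sorted pair, union methods and sources -------------------------------------
oracle_consolidate <- function(records) {
  env <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(records))) {
    a <- records$interactor_a[i]
    b <- records$interactor_b[i]
    key <- paste(sort(c(a, b)), collapse = "\r")
    prev <- if (exists(key, envir = env)) get(key, envir = env)
            else list(methods = character(), sources = character())
    assign(key, list(
      methods = union(prev$methods, records$methods[[i]]),
      sources = union(prev$sources, records$source[i])), envir = env)
  }
  keys <- sort(ls(env))
  out <- lapply(keys, function(k) {
    pair <- strsplit(k, "\r", fixed = TRUE)[[1]]
    v <- get(k, envir = env)
    list(gene_a = pair[1], gene_b = pair[2],
         methods = sort(v$methods), sources = sort(v$sources))
  })
  out
}

# compare an interactome tibble against the oracle's edge list
expect_matches_oracle <- function(net, oracle) {
  expect_equal(nrow(net), length(oracle))
  for (i in seq_along(oracle)) {
    expect_equal(net$gene_a[i], oracle[[i]]$gene_a)
    expect_equal(net$gene_b[i], oracle[[i]]$gene_b)
    expect_equal(sort(net$methods[[i]]), oracle[[i]]$methods)
    expect_equal(sort(net$sources[[i]]), oracle[[i]]$sources)
  }
}

# --- scoring oracle: direct enumeration of the two-step scheme ---------------
# annotated: character vector; grouping: named accession -> label vector
oracle_score <- function(net, annotated, grouping, alpha = 1, prior = 0.5) {
  to_groups <- function(methods) {
    unique(vapply(methods, function(m) {
      if (m %in% names(grouping)) unname(grouping[[m]]) else m
    }, character(1)))
  }
  pos <- logical(nrow(net)); neg <- logical(nrow(net))
  for (i in seq_len(nrow(net))) {
    a_in <- net$gene_a[i] %in% annotated
    b_in <- net$gene_b[i] %in% annotated
    pos[i] <- a_in && b_in
    neg[i] <- !a_in && !b_in
  }
  groups <- sort(unique(unlist(lapply(net$methods, to_groups))))
  lr <- numeric(0)
  for (g in groups) {
    tp <- 0; fp <- 0
    for (i in seq_len(nrow(net))) {
      if (g %in% to_groups(net$methods[[i]])) {
        if (pos[i]) tp <- tp + 1
        if (neg[i]) fp <- fp + 1
      }
    }
    lr[g] <- ((tp + alpha) / (sum(pos) + 2 * alpha)) /
             ((fp + alpha) / (sum(neg) + 2 * alpha))
  }
  weights <- numeric(nrow(net))
  for (i in seq_len(nrow(net))) {
    L <- 1
    for (g in to_groups(net$methods[[i]])) L <- L * lr[[g]]
    weights[i] <- prior * L / (prior * L + (1 - prior))
  }
  list(lr = lr, weights = weights, n_pos = sum(pos), n_neg = sum(neg),
       n_mixed = sum(!pos & !neg))
}

# --- graph-statistics oracle: adjacency matrix, BFS components, triangle
# counting by triple enumeration ----------------------------------------------
oracle_graph_stats <- function(edges) {
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    a <- edges$gene_a[i]; b <- edges$gene_b[i]
    if (a != b) { adj[a, b] <- TRUE; adj[b, a] <- TRUE }
  }
  # components by BFS (self-loops do not affect connectivity)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (u in seq_len(n)) {
        if (adj[v, u] && is.na(comp[u])) { comp[u] <- cur; queue <- c(queue, u) }
      }
    }
  }
  # local clustering by triangle enumeration
  cc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ])
    d <- length(nb)
    if (d < 2) { cc[v] <- 0; next }
    tri <- 0
    for (i in seq_len(d - 1)) for (j in (i + 1):d) {
      if (adj[nb[i], nb[j]]) tri <- tri + 1
    }
    cc[v] <- 2 * tri / (d * (d - 1))
  }
  list(n_nodes = n, n_components = max(comp, 0L),
       avg_clustering = if (n == 0) 0 else mean(cc),
       degree = rowSums(adj))
}

# --- random-input builders ----------------------------------------------------
random_records <- function(n, n_genes = 6, methods = c("MI:0018", "MI:0006",
                                                       "MI:0007", "MI:0004"),
                           sources = c("dbA", "dbB", "dbC"),
                           self_loops = TRUE) {
  genes <- sprintf("G%02d", seq_len(n_genes))
  a <- sample(genes, n, replace = TRUE)
  b <- sample(genes, n, replace = TRUE)
  if (!self_loops) {
    while (any(a == b)) b[a == b] <- sample(genes, sum(a == b), replace = TRUE)
  }
  tibble::tibble(
    interactor_a = a, interactor_b = b,
    methods = lapply(seq_len(n), function(i)
      sample(methods, sample(1:3, 1))),
    source = sample(sources, n, replace = TRUE))
}

random_graph_edges <- function(n_nodes, p = 0.2) {
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  pairs <- t(utils::combn(nodes, 2))
  keep <- stats::runif(nrow(pairs)) < p
  pairs <- pairs[keep, , drop = FALSE]
  tibble::tibble(gene_a = pairs[, 1], gene_b = pairs[, 2],
                 methods = rep(list("MI:0018"), nrow(pairs)),
                 sources = rep(list("db"), nrow(pairs)))
}

# small in-memory annotation set used across scoring/filtering tests
toy_annotations <- function() {
  annotation_set(
    tibble::tibble(
      gene = c("G1", "G2", "G3", "G4", "G5", "G5"),
      term = c("GO:0000001", "GO:0000001", "GO:0000002", "GO:0000002",
               "GO:0000001", "GO:0000002"),
      evidence = c("IDA", "IDA", "IEA", "IDA", "IEA", "TAS")),
    descriptions = tibble::tibble(
      term = c("GO:0000001", "GO:0000002"),
      description = c("signal transduction", "signaling receptor binding")))
}

toy_net <- function() {
  recs <- tibble::tibble(
    interactor_a = c("G1", "G3", "G1", "G2"),
    interactor_b = c("G2", "G4", "G3", "G5"),
    methods = list("MI:0018", c("MI:0006", "MI:0018"), "MI:0007", "MI:0018"),
    source = "db")
  build_interactome(recs)
}
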