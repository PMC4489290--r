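# Two-step Bayesian reliability scoring

test_that("method grouping maps variants to combined labels with identity fallback", {
  expect_equal(group_methods(c("MI:0006", "MI:0007")), "coimmunoprecipitation")
  expect_equal(group_methods("MI:0018"), "two hybrid")
  expect_equal(group_methods("MI:0096"), "MI:0096")  # ungrouped accession
  expect_equal(group_methods(character()), character())
  custom <- c("MI:0001" = "lab A assay")
  expect_equal(group_methods(c("MI:0001", "MI:0002"), custom),
               sort(c("lab A assay", "MI:0002")))
})

test_that("grouping tables load from TSV and YAML", {
  ft <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("accession\tgroup", "MI:0006\tcoip", "MI:0007\tcoip"), ft)
  g <- read_method_grouping(ft)
  expect_equal(unname(g[c("MI:0006", "MI:0007")]), c("coip", "coip"))
  fy <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("'MI:0018': two hybrid"), fy)
  expect_equal(unname(read_method_grouping(fy)["MI:0018"]), "two hybrid")
})

test_that("reference sets follow the three-case endpoint rule and partition edges", {
  ann <- toy_annotations()  # GO:0000001 annotates G1, G2, G5
  recs <- tibble::tibble(
    interactor_a = c("G1", "G3", "G1"),
    interactor_b = c("G2", "G4", "G3"),
    methods = list("MI:0018", "MI:0018", "MI:0018"), source = "db")
  net <- build_interactome(recs)
  refs <- build_reference_sets(net, ann, "GO:0000001")
  # both endpoints annotated -> positive; neither -> negative; one -> mixed
  pos_pair <- paste(net$gene_a[refs$positive], net$gene_b[refs$positive])
  neg_pair <- paste(net$gene_a[refs$negative], net$gene_b[refs$negative])
  expect_equal(pos_pair, "G1 G2")
  expect_equal(neg_pair, "G3 G4")
  expect_equal(refs$n_mixed, 1L)
  expect_equal(refs$n_positive + refs$n_negative + refs$n_mixed, nrow(net))
})

test_that("degenerate reference sets abort with actionable guidance", {
  ann <- toy_annotations()
  # every edge touches only annotated genes -> empty negative set
  net <- build_interactome(tibble::tibble(
    interactor_a = "G1", interactor_b = "G2",
    methods = list("MI:0018"), source = "db"))
  expect_error(build_reference_sets(net, ann, "GO:0000001"),
               "broaden or narrow")
})

test_that("method likelihood ratios follow the pseudocounted ratio formula", {
  # |P| = 3, |N| = 3; method m on 2 positives and 1 negative, alpha = 1:
  # lr = ((2+1)/(3+2)) / ((1+1)/(3+2)) = (3/5)/(2/5) = 1.5
  ann <- annotation_set(tibble::tibble(
    gene = c("A1", "A2", "A3", "A4"), term = "GO:0000001", evidence = "IDA"))
  recs <- tibble::tibble(
    interactor_a = c("A1", "A1", "A2", "B1", "B3", "B5"),
    interactor_b = c("A2", "A3", "A4", "B2", "B4", "B6"),
    methods = list(c("MI:0018", "MI:0096"), c("MI:0018", "MI:0096"), "MI:0018",
                   c("MI:0018", "MI:0096"), "MI:0018", "MI:0018"),
    source = "db")
  net <- build_interactome(recs)
  refs <- build_reference_sets(net, ann, "GO:0000001")
  expect_equal(refs$n_positive, 3L)
  expect_equal(refs$n_negative, 3L)
  scores <- score_methods(net, refs)
  expect_equal(scores$lr[scores$group == "MI:0096"], 1.5)
  # a method on every edge of balanced sets is uninformative
  expect_equal(scores$lr[scores$group == "two hybrid"], 1)
})

test_that("posterior weights follow the naive-Bayes odds form", {
  scores <- structure(
    tibble::tibble(group = c("m1", "m2"), tp = c(0L, 0L), fp = c(0L, 0L),
                   lr = c(1.5, 1)),
    class = c("ppi_method_scores", class(tibble::tibble())),
    pseudocount = 1, prior = 0.5, n_positive = 1, n_negative = 1)
  # single method, lr 1.5, prior 0.5 -> 1.5 / 2.5 = 0.6
  expect_equal(score_interaction("m1", scores), 0.6)
  # all-neutral evidence returns the prior
  expect_equal(score_interaction("m2", scores), 0.5)
  attr(scores, "prior") <- 0.2
  expect_equal(score_interaction("m2", scores), 0.2)
  # an unseen group is neutral, with a warning
  expect_warning(w <- score_interaction(c("m1", "m9"), scores), "lr = 1")
  expect_equal(w, 1.5 * 0.2 / (1.5 * 0.2 + 0.8))
})

test_that("two variants of one combined method weigh the same as either alone", {
  ann <- annotation_set(tibble::tibble(
    gene = c("A1", "A2", "A3", "A4"), term = "GO:0000001", evidence = "IDA"))
  base <- tibble::tibble(
    interactor_a = c("A1", "A2", "B1", "B3"),
    interactor_b = c("A2", "A3", "B2", "B4"),
    methods = list("MI:0006", "MI:0018", "MI:0018", "MI:0006"),
    source = "db")
  variants <- list(
    list("MI:0006"),                      # anti bait coip alone
    list("MI:0007"),                      # anti tag coip alone
    list(c("MI:0006", "MI:0007")))        # both variants on the edge
  weights <- vapply(variants, function(m) {
    recs <- base
    recs$methods[1] <- m
    net <- build_interactome(recs)
    refs <- build_reference_sets(net, ann, "GO:0000001")
    sc <- score_methods(net, refs)
    net$weight <- NA_real_
    score_interaction(group_methods(net$methods[[1]]), sc)
  }, numeric(1))
  expect_equal(weights[1], weights[2])
  expect_equal(weights[1], weights[3])
})

test_that("lr and weights match brute-force enumeration on small random interactomes", {
  set.seed(21)
  grouping <- default_method_grouping()
  for (rep in 1:40) {
    recs <- random_records(sample(5:20, 1), n_genes = 8, self_loops = FALSE)
    net <- build_interactome(recs)
    genes <- unique(c(net$gene_a, net$gene_b))
    annotated <- sample(genes, max(2, floor(length(genes) / 2)))
    ann <- annotation_set(tibble::tibble(
      gene = annotated, term = "GO:0000123", evidence = "IDA"))
    refs <- tryCatch(build_reference_sets(net, ann, "GO:0000123"),
                     error = function(e) NULL)
    if (is.null(refs)) next  # degenerate draw: no positive or negative edge
    scores <- score_methods(net, refs, grouping = grouping)
    oracle <- oracle_score(net, annotated, grouping)
    expect_equal(refs$n_positive, oracle$n_pos)
    expect_equal(refs$n_negative, oracle$n_neg)
    expect_equal(stats::setNames(scores$lr, scores$group),
                 oracle$lr[sort(names(oracle$lr))], tolerance = 1e-12)
    scored <- score_interactome(net, ann, "GO:0000123", grouping = grouping)
    expect_equal(scored$weight, oracle$weights, tolerance = 1e-12)
  }
})

test_that("weights are strictly monotone in added favorable evidence", {
  ann <- toy_annotations()
  recs <- tibble::tibble(
    interactor_a = c("G1", "G1", "G3", "G6"),
    interactor_b = c("G2", "G5", "G4", "G7"),
    methods = list(c("MI:0006", "MI:0018"), "MI:0006", "MI:0018", "MI:0018"),
    source = "db")
  net <- build_interactome(recs)
  scored <- score_interactome(net, ann, "GO:0000001")
  sc <- attr(scored, "method_scores")
  lr <- stats::setNames(sc$lr, sc$group)
  expect_gt(lr[["coimmunoprecipitation"]], 1)
  # adding an lr>1 method to a two-hybrid-only edge strictly increases weight
  w_th <- score_interaction("two hybrid", sc)
  w_both <- score_interaction(c("two hybrid", "coimmunoprecipitation"), sc)
  expect_gt(w_both, w_th)
  # the joint ratio is permutation-invariant
  expect_equal(score_interaction(c("coimmunoprecipitation", "two hybrid"), sc),
               w_both)
  # single-method edges: weight > 0.5 iff lr > 1 (prior 0.5)
  for (g in sc$group) {
    w <- score_interaction(g, sc)
    expect_equal(w > 0.5, lr[[g]] > 1)
  }
})

test_that("scored interactomes have weights in (0,1) and a conserved histogram", {
  ann <- toy_annotations()
  recs <- tibble::tibble(
    interactor_a = c("G1", "G3", "G6", "G1"),
    interactor_b = c("G2", "G4", "G7", "G5"),
    methods = list("MI:0018", c("MI:0006", "MI:0018"), "MI:0018", "MI:0007"),
    source = "db")
  net <- build_interactome(recs)
  scored <- score_interactome(net, ann, "GO:0000001")
  expect_true(all(scored$weight > 0 & scored$weight < 1))
  hist <- attr(scored, "weight_histogram")
  expect_equal(nrow(hist), 20L)
  expect_equal(sum(hist$count), nrow(scored))
  # all edges sharing one method profile share one weight
  uniform <- build_interactome(tibble::tibble(
    interactor_a = c("G1", "G3", "G6"), interactor_b = c("G2", "G4", "G7"),
    methods = list("MI:0018", "MI:0018", "MI:0018"), source = "db"))
  su <- score_interactome(uniform, ann, "GO:0000001")
  expect_equal(length(unique(su$weight)), 1L)
})

test_that("tidy and glance summarize method scores", {
  ann <- toy_annotations()
  net <- toy_net()
  refs <- build_reference_sets(net, ann, "GO:0000001")
  sc <- score_methods(net, refs)
  td <- tidy(sc)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "ppi_method_scores"))
  gl <- glance(sc)
  expect_equal(gl$n_methods, nrow(sc))
  expect_equal(gl$prior, 0.5)
  expect_equal(gl$max_lr, max(sc$lr))
})
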