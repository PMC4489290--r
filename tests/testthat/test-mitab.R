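# MITAB parsing, experimental-validation filtering and identifier mapping

mitab_row <- function(a, b, method, source = 'psi-mi:"MI:0469"(intact)',
                      n_cols = 15) {
  cols <- rep("-", n_cols)
  cols[1] <- a; cols[2] <- b; cols[7] <- method
  cols[10] <- "taxid:9606"; cols[11] <- "taxid:9606"
  if (n_cols >= 13) cols[13] <- source
  paste(cols, collapse = "\t")
}

test_that("MITAB rows parse into records with method accession sets", {
  lines <- c(
    "#ID(s) interactor A\tID(s) interactor B\t...header comment",
    mitab_row("uniprotkb:P1", "uniprotkb:P2", 'psi-mi:"MI:0018"(two hybrid)'),
    mitab_row("uniprotkb:P3", "uniprotkb:P4",
              'psi-mi:"MI:0006"(anti bait coip)|psi-mi:"MI:0007"(anti tag coip)')
  )
  recs <- parse_mitab_lines(lines)
  expect_equal(nrow(recs), 2L)
  expect_equal(recs$interactor_a, c("P1", "P3"))
  expect_equal(recs$interactor_b, c("P2", "P4"))
  expect_equal(recs$methods[[1]], "MI:0018")
  expect_setequal(recs$methods[[2]], c("MI:0006", "MI:0007"))
  expect_equal(recs$source, c("intact", "intact"))
  expect_equal(recs$taxon_a, c("9606", "9606"))
  expect_equal(attr(recs, "n_skipped"), 0L)
})

test_that("short rows are skipped with a count; empty input gives empty output", {
  lines <- c(mitab_row("a:P1", "a:P2", 'psi-mi:"MI:0018"(x)'),
             "too\tfew\tcolumns")
  expect_warning(recs <- parse_mitab_lines(lines), "fewer than 15")
  expect_equal(nrow(recs), 1L)
  expect_equal(attr(recs, "n_skipped"), 1L)

  empty <- parse_mitab_lines(character())
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "n_skipped"), 0L)
  expect_equal(attr(empty, "n_no_method"), 0L)
})

test_that("free-text methods without accessions are counted and cross-species rows can be dropped", {
  lines <- c(mitab_row("a:P1", "a:P2", "two hybrid (no accession)"),
             mitab_row("a:P3", "a:P4", 'psi-mi:"MI:0018"(two hybrid)'))
  expect_warning(recs <- parse_mitab_lines(lines), "no MI:NNNN")
  expect_equal(attr(recs, "n_no_method"), 1L)
  expect_equal(recs$methods[[1]], character())

  cross <- paste(c("a:P1", "a:P2", rep("-", 4), 'psi-mi:"MI:0018"(th)', "-",
                   "-", "taxid:9606", "taxid:10090", "-", "db", "-", "-"),
                 collapse = "\t")
  recs2 <- parse_mitab_lines(cross, same_taxon_only = TRUE)
  expect_equal(nrow(recs2), 0L)
  recs3 <- parse_mitab_lines(cross)
  expect_equal(nrow(recs3), 1L)
})

test_that("experimental filter keeps whitelist intersections and counts discards", {
  recs <- tibble::tibble(
    interactor_a = c("P1", "P2", "P3"),
    interactor_b = c("Q1", "Q2", "Q3"),
    methods = list("MI:0018", "MI:0063", c("MI:0018", "MI:0063")),
    source = "db")
  wl <- c("MI:0018", "MI:0006")
  kept <- suppressMessages(filter_experimental(recs, wl))
  expect_equal(nrow(kept), 2L)
  expect_equal(attr(kept, "n_discarded"), 1L)
  # methods reduced to the whitelisted subset
  expect_equal(kept$methods[[2]], "MI:0018")
  # kept + discarded partitions the input
  expect_equal(nrow(kept) + attr(kept, "n_discarded"), nrow(recs))
})

test_that("identifier mapping multiplies one-to-many records and drops unmappable ones", {
  idmap <- tibble::tibble(raw_id = c("P1", "P1", "P2", "P3"),
                          gene_id = c("G1", "G3", "G2", "G4"))
  recs <- tibble::tibble(
    interactor_a = c("P1", "P3", "PX"),
    interactor_b = c("P2", "P2", "P2"),
    methods = list("MI:0018", "MI:0018", "MI:0018"),
    source = "db")
  out <- suppressMessages(map_identifiers(recs, idmap))
  expect_equal(attr(out, "n_unmapped"), 1L)
  expect_equal(nrow(out), 3L)  # 2 (cross product) + 1
  expect_setequal(paste(out$interactor_a, out$interactor_b),
                  c("G1 G2", "G3 G2", "G4 G2"))
})

test_that("mapping output size equals the sum of mapping-set products", {
  set.seed(42)
  for (rep in 1:20) {
    recs <- random_records(8)
    raw <- unique(c(recs$interactor_a, recs$interactor_b))
    # random multiplicity 0-3 per raw id
    idmap <- purrr::map_dfr(raw, function(r) {
      k <- sample(0:3, 1)
      if (k == 0) return(NULL)
      tibble::tibble(raw_id = r, gene_id = paste0(r, "_m", seq_len(k)))
    })
    out <- suppressMessages(map_identifiers(recs, idmap))
    mult <- function(x) {
      k <- sum(idmap$raw_id == x)
      k
    }
    expected <- sum(vapply(seq_len(nrow(recs)), function(i) {
      mult(recs$interactor_a[i]) * mult(recs$interactor_b[i])
    }, numeric(1)))
    expect_equal(nrow(out), expected)
  }
})

test_that("parse -> serialize -> parse round-trips retained fields exactly", {
  set.seed(99)
  recs <- random_records(15)
  recs$taxon_a <- "9606"
  recs$taxon_b <- sample(c("9606", NA), 15, replace = TRUE)
  f <- withr::local_tempfile(fileext = ".mitab")
  write_mitab(recs, f)
  back <- read_mitab(f)
  expect_equal(back$interactor_a, recs$interactor_a)
  expect_equal(back$interactor_b, recs$interactor_b)
  expect_equal(lapply(back$methods, sort), lapply(recs$methods, sort))
  expect_equal(back$source, recs$source)
  expect_equal(back$taxon_a, recs$taxon_a)
  expect_equal(back$taxon_b, recs$taxon_b)
  # serialize -> parse -> serialize is bit-identical on disk
  f2 <- withr::local_tempfile(fileext = ".mitab")
  f3 <- withr::local_tempfile(fileext = ".mitab")
  write_mitab(back, f2)
  write_mitab(read_mitab(f2), f3)
  expect_identical(readLines(f2), readLines(f3))
})

test_that("whitelist configs load from YAML and TSV and reject malformed accessions", {
  fy <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("accepted:", "  - 'MI:0018'", "  - 'MI:0006'"), fy)
  expect_setequal(read_method_whitelist(fy), c("MI:0018", "MI:0006"))

  ft <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("accession", "MI:0018", "MI:0114"), ft)
  expect_setequal(read_method_whitelist(ft), c("MI:0018", "MI:0114"))

  fb <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("accession", "two hybrid"), fb)
  expect_error(read_method_whitelist(fb), "not MI:NNNN")
})
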