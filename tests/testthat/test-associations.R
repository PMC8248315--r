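test_that("evidence-code filter drops IEA/ND and keeps the rest", {
  go <- tibble::tibble(entity_id = "g1", class_id = c("GO:1", "GO:2"),
                       evidence = c("IEA", "IDA"))
  out <- filter_go_annotations(go)
  expect_equal(nrow(out), 1)
  expect_equal(out$class_id, "GO:2")
  expect_equal(out$relation, "has-function")

  expect_equal(nrow(filter_go_annotations(go[0, ])), 0)

  set.seed(1)
  rec <- tibble::tibble(entity_id = paste0("g", 1:10),
                        class_id = paste0("GO:", 1:10),
                        evidence = c(rep("ND", 4), rep("EXP", 6)))
  expect_equal(nrow(filter_go_annotations(rec)), 6)
  expect_error(filter_go_annotations(rec[, 1:2]), "evidence")
})

test_that("expression thresholding is inclusive at 4.0 TPM", {
  tpm <- matrix(c(3.9, 4.0, 4.1, 0), 2, 2, byrow = TRUE,
                dimnames = list(c("g1", "g2"), c("t1", "t2")))
  out <- threshold_expression(tpm)
  expect_equal(paste(out$entity_id, out$class_id),
               c("g1 t2", "g2 t1"))
  expect_equal(unique(out$relation), "expressed-in")

  zeros <- matrix(0, 3, 2, dimnames = list(paste0("g", 1:3), c("t1", "t2")))
  expect_equal(nrow(threshold_expression(zeros)), 0)

  neg <- matrix(-1, 1, 1, dimnames = list("g", "t"))
  expect_error(threshold_expression(neg), "non-negative")
})

test_that("expression association count matches a brute-force cell scan", {
  set.seed(42)
  tpm <- matrix(stats::runif(100, 0, 8), 20, 5,
                dimnames = list(sprintf("g%02d", 1:20), sprintf("t%d", 1:5)))
  brute <- 0
  for (i in 1:20) for (j in 1:5) if (tpm[i, j] >= 4.0) brute <- brute + 1
  expect_equal(nrow(threshold_expression(tpm)), brute)
})

test_that("unmapped tissues are skipped with a message", {
  tpm <- matrix(5, 1, 2, dimnames = list("g1", c("liver", "weird_tissue")))
  expect_message(
    out <- threshold_expression(tpm, tissue_map = c(liver = "AN:1")),
    "weird_tissue")
  expect_equal(out$class_id, "AN:1")
})

test_that("interaction filter keeps confidence >= 700 and dedups unordered pairs", {
  edges <- tibble::tibble(entity_a = c("a", "a"), entity_b = c("b", "c"),
                          confidence = c(699L, 700L))
  out <- filter_interactions(edges)
  expect_equal(nrow(out), 1)
  expect_equal(out$entity_b, "c")

  dup <- tibble::tibble(entity_a = c("a", "b"), entity_b = c("b", "a"),
                        confidence = c(900L, 900L))
  expect_equal(nrow(filter_interactions(dup)), 1)

  set.seed(7)
  big <- tibble::tibble(entity_a = sample(letters, 1000, TRUE),
                        entity_b = sample(LETTERS, 1000, TRUE),
                        confidence = sample(0:1000, 1000, TRUE))
  brute <- big[big$confidence >= 700, ]
  brute_pairs <- unique(paste(pmin(brute$entity_a, brute$entity_b),
                              pmax(brute$entity_a, brute$entity_b)))
  expect_equal(nrow(filter_interactions(big)), length(brute_pairs))
})

test_that("self-interactions are retained but reported", {
  edges <- tibble::tibble(entity_a = c("a", "b"), entity_b = c("a", "c"),
                          confidence = c(800L, 800L))
  expect_message(out <- filter_interactions(edges), "self-interaction")
  expect_equal(nrow(out), 2)
})

test_that("ortholog mapping rewrites, drops unmapped and dedups many-to-one", {
  assocs <- tibble::tibble(entity_id = "mGene1", relation = "has-phenotype",
                           class_id = "MP:1")
  map <- tibble::tibble(source_id = "mGene1", target_id = "hGene1")
  out <- map_orthologs(assocs, map)
  expect_equal(out$entity_id, "hGene1")
  expect_equal(out$class_id, "MP:1")

  empty_map <- tibble::tibble(source_id = character(),
                              target_id = character())
  expect_message(out2 <- map_orthologs(assocs, empty_map), "dropped 1")
  expect_equal(nrow(out2), 0)
  expect_equal(attr(out2, "n_dropped"), 1)

  # two mouse genes collapsing onto one human gene, same class
  assocs3 <- tibble::tibble(entity_id = c("m1", "m2"),
                            relation = "has-phenotype",
                            class_id = "MP:9")
  map3 <- tibble::tibble(source_id = c("m1", "m2"), target_id = "h1")
  out3 <- map_orthologs(assocs3, map3)
  expect_equal(nrow(out3), 1)
  expect_equal(out3$entity_id, "h1")
})

test_that("every filter is idempotent and never grows its input", {
  set.seed(11)
  rec <- tibble::tibble(entity_id = sample(paste0("g", 1:20), 50, TRUE),
                        class_id = sample(paste0("GO:", 1:30), 50, TRUE),
                        evidence = sample(c("IEA", "ND", "IDA", "EXP"), 50,
                                          TRUE))
  once <- filter_go_annotations(rec)
  twice <- filter_go_annotations(
    dplyr::mutate(once, evidence = sub("^evidence:", "", source)))
  expect_equal(once[, c("entity_id", "relation", "class_id")],
               twice[, c("entity_id", "relation", "class_id")])
  expect_lte(nrow(once), nrow(rec))

  edges <- tibble::tibble(entity_a = sample(letters, 200, TRUE),
                          entity_b = sample(letters, 200, TRUE),
                          confidence = sample(0:1000, 200, TRUE))
  once_e <- suppressMessages(filter_interactions(edges))
  twice_e <- suppressMessages(filter_interactions(once_e))
  expect_equal(once_e, twice_e)
  expect_lte(nrow(once_e), nrow(edges))

  tpm <- matrix(stats::runif(60, 0, 8), 10, 6,
                dimnames = list(paste0("g", 1:10), paste0("t", 1:6)))
  out_t <- threshold_expression(tpm)
  expect_lte(nrow(out_t), length(tpm))
})

test_that("association tables round-trip through TSV", {
  assocs <- tibble::tibble(entity_id = c("g1", "d1"),
                           relation = c("has-function", "has-phenotype"),
                           class_id = c("GO:1", "MP:2"),
                           source = "synthetic")
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(assocs, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_associations(f)
  expect_equal(back$entity_id, assocs$entity_id)
  expect_equal(back$class_id, assocs$class_id)
})
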