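test_that("folds partition diseases with disjoint test sets", {
  diseases <- sprintf("d%03d", 1:100)
  folds <- make_folds(diseases, folds = 10, seed = 3)
  test_sets <- split(folds$disease[folds$role == "test"],
                     folds$fold[folds$role == "test"])
  expect_true(all(lengths(test_sets) == 10))
  expect_equal(sort(unname(unlist(test_sets))), sort(diseases))  # disjoint + total
  # within every fold the roles partition the whole universe
  for (f in 1:10) {
    sub <- folds[folds$fold == f, ]
    expect_setequal(sub$disease, diseases)
    expect_equal(sum(sub$role == "validation"), 9)  # ~10% of the 90 rest
  }
  expect_identical(make_folds(diseases, 10, seed = 3),
                   make_folds(diseases, 10, seed = 3))
  expect_error(make_folds(sprintf("d%d", 1:5), folds = 10), "at least")
})

test_that("negative sampling avoids positives and hits the requested count", {
  positives <- tibble::tibble(gene = c("g1", "g2"), disease = "d1")
  universe <- sprintf("g%03d", 1:100)
  negs <- sample_negatives(positives, c(universe, "g1", "g2"), k = 20,
                           seed = 1)
  expect_equal(nrow(negs), 40)
  expect_false(any(negs$gene %in% positives$gene))
  expect_equal(anyDuplicated(paste(negs$gene, negs$disease)), 0)
  expect_error(sample_negatives(positives, sprintf("g%d", 1:10), k = 20),
               "too small")
})

test_that("negative sampling is uniform over eligible genes", {
  # 2000 diseases x 5 draws each = 10^4 independent uniform draws from the
  # 20 eligible genes
  positives <- tibble::tibble(gene = "g01",
                              disease = sprintf("d%04d", 1:2000))
  universe <- sprintf("g%02d", 1:21)   # 20 eligible after excluding g01
  draws <- sample_negatives(positives, universe, k = 5, seed = 7)$gene
  expect_length(draws, 10000)
  freq <- table(draws) / length(draws)
  expect_equal(length(freq), 20)
  p <- 1 / 20
  se <- sqrt(p * (1 - p) / length(draws))
  expect_true(all(abs(freq - p) < 3 * se + 1e-3))
})

fixture_embeddings <- function(dim = 24, seed = 42) {
  # paired geometry: disease vectors near the mean of their genes
  withr::with_seed(seed, {
    genes <- sprintf("g%03d", 1:120)
    diseases <- sprintf("d%02d", 1:20)
    emb_g <- matrix(stats::rnorm(120 * dim), 120, dim,
                    dimnames = list(genes, NULL))
    gold <- tibble::tibble(gene = sample(genes, 40),
                           disease = rep(diseases, each = 2))
    emb_d <- t(sapply(split(gold$gene, gold$disease), function(gs) {
      colMeans(emb_g[gs, , drop = FALSE]) + stats::rnorm(dim, sd = 0.3)
    }))
    emb <- rbind(emb_g, emb_d[diseases, ])
    class(emb) <- c("embedding_table", "matrix", "array")
    list(emb = emb, gold = gold, genes = genes, diseases = diseases)
  })
}

test_that("training learns a generalizing ranking on paired embeddings", {
  fx <- fixture_embeddings()
  cfg <- ranker_config(folds = 5, epochs = 40, seed = 1)
  fit <- fit_ranker(fx$gold, fx$emb, fx$genes, config = cfg)
  td <- tidy(fit)
  expect_equal(nrow(td), 5)
  # the selected epoch separates validation positives from negatives
  expect_gt(mean(td$val_auc), 0.7)
  # the training curve descends: some epoch beats the epoch-0 loss
  for (f in fit$folds) {
    expect_lt(min(f$history$val_loss), f$history$val_loss[1])
  }
})

test_that("test diseases never appear in a fold's training or validation data", {
  fx <- fixture_embeddings()
  folds <- make_folds(fx$diseases, 5, seed = 2)
  for (f in 1:5) {
    sub <- folds[folds$fold == f, ]
    expect_length(intersect(sub$disease[sub$role == "test"],
                            sub$disease[sub$role != "test"]), 0)
  }
})

test_that("scores are strictly inside (0,1) and evaluation mode is deterministic", {
  fx <- fixture_embeddings()
  cfg <- ranker_config(folds = 5, epochs = 5, seed = 1)
  fit <- fit_ranker(fx$gold, fx$emb, fx$genes, config = cfg)
  d <- fit$folds[[1]]$test_diseases[1]
  s1 <- score_genes(fit, fx$genes, d, fx$emb)
  s2 <- score_genes(fit, fx$genes, d, fx$emb)
  expect_true(all(s1$score > 0 & s1$score < 1))
  expect_identical(s1, s2)
})

test_that("the score is not symmetric in its two inputs", {
  fx <- fixture_embeddings()
  cfg <- ranker_config(folds = 5, epochs = 5, seed = 1)
  fit <- fit_ranker(fx$gold, fx$emb, fx$genes, config = cfg)
  model <- fit$folds[[1]]$model
  x <- lookup_embeddings(fx$emb, fx$genes[1])
  y <- lookup_embeddings(fx$emb, fx$diseases[1])
  s_xy <- ontorank:::model_forward(model, x, y, cfg)$score
  s_yx <- ontorank:::model_forward(model, y, x, cfg)$score
  expect_false(isTRUE(all.equal(s_xy, s_yx)))
})

test_that("training is exactly reproducible for fixed seeds", {
  fx <- fixture_embeddings()
  cfg <- ranker_config(folds = 5, epochs = 8, seed = 11)
  f1 <- fit_ranker(fx$gold, fx$emb, fx$genes, config = cfg)
  f2 <- fit_ranker(fx$gold, fx$emb, fx$genes, config = cfg)
  expect_identical(tidy(f1)$val_loss, tidy(f2)$val_loss)
  expect_identical(f1$folds[[1]]$model, f2$folds[[1]]$model)
})

test_that("missing embeddings are reported by id", {
  fx <- fixture_embeddings()
  gold_bad <- dplyr::bind_rows(fx$gold,
                               tibble::tibble(gene = "ghost_gene",
                                              disease = fx$diseases[1]))
  expect_error(fit_ranker(gold_bad, fx$emb, fx$genes,
                          config = ranker_config(folds = 5)),
               "ghost_gene")
})
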