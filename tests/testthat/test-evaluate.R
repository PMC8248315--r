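make_ranking <- function(df) {
  # df: disease, gene, score, label
  rank_genes(df[, c("disease", "gene", "score")],
             df[df$label == 1, c("gene", "disease")])
}

test_that("a perfect ranking has area 1 and hits at rank 1", {
  df <- tibble::tibble(disease = "d1", gene = paste0("g", 1:10),
                       score = seq(1, 0.1, length.out = 10),
                       label = c(1, 1, rep(0, 8)))
  r <- make_ranking(df)
  roc <- roc_curve_macro(r)
  expect_equal(roc$per_disease$auc, 1.0)
  expect_equal(roc$auc_macro, 1.0)
  h <- hits_at_n(r, c(1, 2, 10))
  expect_equal(h$hits, c(0.5, 1, 1))
})

test_that("per-disease area equals brute-force pair counting on random scores", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(10:40, 1)
    score <- round(stats::runif(n), 2)       # rounding forces ties
    label <- as.integer(stats::runif(n) < 0.3)
    if (sum(label) == 0 || sum(label) == n) next
    df <- tibble::tibble(disease = "d", gene = sprintf("g%03d", 1:n),
                         score = score, label = label)
    r <- make_ranking(df)
    expect_equal(roc_curve_macro(r)$per_disease$auc,
                 oracle_auc_pairs(score, label), tolerance = 1e-9)
  }
})

test_that("macro curve area averages per-disease performance on a shared universe", {
  # disease 1: both positives on top (area 1); disease 2: alternating with
  # positives exactly mid-ranked (area 0.5)
  df <- dplyr::bind_rows(
    tibble::tibble(disease = "d1", gene = paste0("g", 1:8),
                   score = 8:1, label = c(1, 1, rep(0, 6))),
    tibble::tibble(disease = "d2", gene = paste0("g", 1:8),
                   score = 8:1, label = c(0, 0, 0, 1, 1, 0, 0, 0)))
  roc <- roc_curve_macro(make_ranking(df))
  expect_equal(sort(roc$per_disease$auc), c(0.5, 1.0))
  expect_equal(roc$auc_macro, 0.75, tolerance = 1e-9)
})

test_that("zero-positive diseases are excluded with a warning", {
  df <- dplyr::bind_rows(
    tibble::tibble(disease = "d1", gene = paste0("g", 1:4),
                   score = 4:1, label = c(1, 0, 0, 0)),
    tibble::tibble(disease = "d2", gene = paste0("g", 1:4),
                   score = 4:1, label = 0))
  r <- rank_genes(df[, c("disease", "gene", "score")],
                  df[df$label == 1, c("gene", "disease")])
  expect_warning(roc <- roc_curve_macro(r), "excluding 1")
  expect_equal(roc$per_disease$disease, "d1")
})

test_that("hits thresholds count ranks inclusively and are monotone", {
  df <- tibble::tibble(disease = "d", gene = sprintf("g%02d", 1:50),
                       score = 50:1, label = c(rep(0, 10), 1, rep(0, 39)))
  r <- make_ranking(df)
  h <- hits_at_n(r, c(1, 10, 100))
  expect_equal(h$hits, c(0, 0, 1))  # rank 11 misses Hits@10, counts for @100

  set.seed(8)
  for (i in 1:20) {
    n <- 60
    df <- tibble::tibble(disease = "d", gene = sprintf("g%02d", 1:n),
                         score = stats::runif(n),
                         label = as.integer(stats::runif(n) < 0.2))
    if (sum(df$label) == 0) next
    r <- make_ranking(df)
    h <- hits_at_n(r, c(1, 5, 10, 25, 60))
    expect_true(all(diff(h$hits) >= 0))
    # brute-force rank scan
    ord <- order(-df$score, df$gene)
    brute <- mean(which(df$label[ord] == 1) <= 10)
    expect_equal(h$hits[h$n == 10], brute)
  }
})

test_that("area is antisymmetric under score negation and invariant to monotone maps", {
  set.seed(5)
  score <- stats::runif(30)
  label <- c(rep(1, 8), rep(0, 22))
  auc <- ontorank:::auc_from_scores(score, label)
  expect_equal(ontorank:::auc_from_scores(-score, label), 1 - auc)
  expect_equal(ontorank:::auc_from_scores(stats::qlogis(score), label), auc)
  expect_equal(ontorank:::auc_from_scores(100 * score + 7, label), auc)
})

test_that("identical rank vectors give p = 1 in the model comparison", {
  r <- c(5, 9, 13, 21, 40)
  out <- compare_models(r, r)
  expect_equal(out$p_value, 1.0)
  expect_false(out$significant)
})

test_that("a strong rank separation is detected as significant", {
  set.seed(2)
  a <- sample(1:50, 100, replace = TRUE)      # model A ranks well
  b <- sample(400:500, 100, replace = TRUE)   # model B ranks poorly
  out <- compare_models(a, b)
  expect_lt(out$p_value, 0.05)
  expect_true(out$significant)
})

test_that("small-sample comparison matches the exact permutation distribution", {
  a <- c(1, 4, 6)
  b <- c(2, 9, 11)
  out <- compare_models(a, b)
  # brute-force permutation distribution of the rank-sum statistic
  pooled <- c(a, b)
  obs_u <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  combos <- utils::combn(6, 3)
  us <- apply(combos, 2, function(idx) {
    aa <- pooled[idx]
    bb <- pooled[-idx]
    sum(outer(aa, bb, ">")) + 0.5 * sum(outer(aa, bb, "=="))
  })
  p_exact <- mean(abs(us - 4.5) >= abs(obs_u - 4.5))
  expect_equal(out$p_value, p_exact, tolerance = 1e-9)
})

test_that("model comparison refuses mismatched association sets", {
  ra <- tibble::tibble(gene = c("g1", "g2"), disease = "d1", rank = c(1, 2))
  rb <- tibble::tibble(gene = c("g1", "g3"), disease = "d1", rank = c(1, 2))
  expect_error(compare_models(ra, rb), "identical association sets")
  expect_error(compare_models(1:3, 1:4), "same associations")
})

test_that("evaluation reports are assembled with fold-wise intervals", {
  df <- dplyr::bind_rows(
    tibble::tibble(disease = "d1", gene = paste0("g", 1:6), score = 6:1,
                   label = c(1, rep(0, 5)), fold = 1L),
    tibble::tibble(disease = "d2", gene = paste0("g", 1:6), score = 6:1,
                   label = c(0, 0, 1, 0, 0, 0), fold = 2L))
  r <- rank_genes(df[, c("disease", "gene", "score")],
                  df[df$label == 1, c("gene", "disease")])
  r$fold <- rep(c(1L, 2L), each = 6)
  rep_ <- evaluate_ranking(r)
  expect_s3_class(rep_, "eval_report")
  expect_equal(rep_$rocauc, mean(rep_$per_disease$auc))
  expect_equal(rep_$rocauc_interval, range(rep_$per_disease$auc))
  g <- glance(rep_)
  expect_true(all(c("rocauc", "hits_at_10") %in% names(g)))
  p <- autoplot(rep_)
  expect_s3_class(p, "ggplot")
})
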