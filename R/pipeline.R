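#' Run the full prioritization pipeline on a benchmark bundle
#'
#' Chains every stage: axiom transformation and graph construction,
#' edge-label-aware random walks, skip-gram embedding, disease-wise
#' cross-validated training of the two-tower ranker, scoring of the full
#' gene universe for every test disease, and macro-averaged evaluation.
#'
#' @param bundle A `synth_bundle` from [generate_benchmark()], or any list
#'   with elements `axioms`, `associations`, `interactions` (may be `NULL`),
#'   `gold` (tibble `gene`, `disease`) and `genes` (candidate universe).
#' @param walks A [walk_config()]; when `NULL`, the regime is chosen from
#'   the bundle (200 walks x 30 steps when interaction edges are present,
#'   80 x 20 otherwise).
#' @param embed An [embed_config()].
#' @param ranker A [ranker_config()].
#' @param shuffle_labels Permute the gold standard's disease column before
#'   training — the negative control that destroys the gene-disease
#'   correspondence while preserving all marginals.
#' @param embeddings Optionally, a precomputed `embedding_table` for this
#'   bundle's graph; skips the walk and training stages (the graph does not
#'   depend on the gold labels, so controls can reuse embeddings).
#' @return A `pipeline_result` list: `report` (an `eval_report`), `ranking`,
#'   `fit`, `embeddings`, `gold` (as trained on).
#' @export
run_pipeline <- function(bundle, walks = NULL,
                         embed = embed_config(), ranker = ranker_config(),
                         shuffle_labels = FALSE, embeddings = NULL) {
  if (is.null(walks)) {
    walks <- walk_config(ppi = !is.null(bundle$interactions) &&
                           nrow(bundle$interactions) > 0)
  }
  if (is.null(embeddings)) {
    g <- build_graph(bundle$axioms, bundle$associations, bundle$interactions)
    corpus <- build_corpus(g, walks)
    embeddings <- train_embeddings(corpus, embed)
  }
  gold <- tibble::as_tibble(bundle$gold)
  if (isTRUE(shuffle_labels)) {
    gold$disease <- withr::with_seed(ranker$seed + 4242L,
                                     sample(gold$disease))
    gold <- dplyr::distinct(gold)
  }
  universe <- intersect(bundle$genes, rownames(embeddings))
  folds <- make_folds(unique(gold$disease), ranker$folds, ranker$val_frac,
                      ranker$seed)
  fit <- fit_ranker(gold, embeddings, universe, folds, ranker)
  scores <- purrr::map_dfr(fit$folds, function(f) {
    purrr::map_dfr(f$test_diseases, function(d) {
      dplyr::mutate(score_genes(fit, universe, d, embeddings, fold = f$fold),
                    fold = f$fold)
    })
  })
  ranking <- rank_genes(scores, gold)
  structure(list(report = evaluate_ranking(ranking), ranking = ranking,
                 fit = fit, embeddings = embeddings, gold = gold),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$report)
  invisible(x)
}
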