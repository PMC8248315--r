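#' Rank candidate genes per disease
#'
#' Orders each disease's candidate genes by descending score, breaking ties
#' by a stable ordering on gene identifier, and attaches the positive labels.
#'
#' @param scores Tibble (`disease`, `gene`, `score`), one row per candidate
#'   pair.
#' @param positives Tibble of true associations (`gene`, `disease`).
#' @return A `ranking_result` tibble (`disease`, `gene`, `score`, `rank`,
#'   `label`), ranked within disease.
#' @export
rank_genes <- function(scores, positives) {
  stopifnot(all(c("disease", "gene", "score") %in% names(scores)),
            all(c("gene", "disease") %in% names(positives)))
  key <- paste(positives$gene, positives$disease, sep = "\r")
  out <- scores |>
    dplyr::mutate(label = as.integer(paste(.data$gene, .data$disease,
                                           sep = "\r") %in% key)) |>
    dplyr::arrange(.data$disease, dplyr::desc(.data$score), .data$gene) |>
    dplyr::group_by(.data$disease) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
  class(out) <- c("ranking_result", class(out))
  out
}

# ROCAUC of one disease's score vector against its labels, computed through
# the rank-sum identity AUC = (R_pos - n_pos (n_pos + 1) / 2) / (n_pos n_neg)
# with tied scores assigned average ranks (equivalently U / (n_pos n_neg)
# with half-credit for ties).
auc_from_scores <- function(score, label) {
  n_pos <- sum(label == 1)
  n_neg <- sum(label == 0)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[label == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Macro-averaged ROC curve and area over diseases
#'
#' At every rank `r` of the (shared) candidate universe, the true and false
#' positive rates of each disease are computed and averaged across diseases;
#' the area under the averaged curve is obtained by the trapezoid rule.
#' Per-disease areas (via the rank-sum identity, ties getting half credit)
#' are reported alongside for significance testing. Diseases without a
#' positive candidate are excluded with a warning.
#'
#' @param ranking A `ranking_result` from [rank_genes()].
#' @return List with `curve` (tibble `rank`, `fpr`, `tpr`), `auc_macro`
#'   (area under the averaged curve), and `per_disease`
#'   (tibble `disease`, `auc`, `n_pos`, `n_neg`).
#' @export
roc_curve_macro <- function(ranking) {
  stopifnot(all(c("disease", "gene", "score", "rank", "label") %in%
                  names(ranking)))
  sizes <- ranking |>
    dplyr::group_by(.data$disease) |>
    dplyr::summarise(n = dplyr::n(), n_pos = sum(.data$label),
                     .groups = "drop")
  empty <- sizes$disease[sizes$n_pos == 0 | sizes$n_pos == sizes$n]
  if (length(empty) > 0) {
    warning("excluding ", length(empty),
            " disease(s) without both positive and negative candidates",
            call. = FALSE)
    ranking <- ranking[!ranking$disease %in% empty, ]
    sizes <- sizes[!sizes$disease %in% empty, ]
  }
  if (nrow(sizes) == 0) stop("no evaluable disease", call. = FALSE)
  if (length(unique(sizes$n)) != 1) {
    stop("macro-averaged curve requires a shared candidate universe ",
         "(equal candidate counts per disease)", call. = FALSE)
  }
  per_disease <- ranking |>
    dplyr::group_by(.data$disease) |>
    dplyr::summarise(auc = auc_from_scores(.data$score, .data$label),
                     n_pos = sum(.data$label),
                     n_neg = dplyr::n() - sum(.data$label),
                     .groups = "drop")
  curve <- ranking |>
    dplyr::arrange(.data$disease, .data$rank) |>
    dplyr::group_by(.data$disease) |>
    dplyr::mutate(tpr = cumsum(.data$label) / sum(.data$label),
                  fpr = cumsum(1 - .data$label) /
                    sum(1 - .data$label)) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$rank) |>
    dplyr::summarise(fpr = mean(.data$fpr), tpr = mean(.data$tpr),
                     .groups = "drop") |>
    dplyr::arrange(.data$rank)
  fpr <- c(0, curve$fpr)
  tpr <- c(0, curve$tpr)
  auc_macro <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(curve = curve, auc_macro = auc_macro, per_disease = per_disease)
}

#' Recall at rank n (Hits\@n)
#'
#' Fraction of true gene-disease associations whose gene ranks within the
#' top `n` candidates for its disease.
#'
#' @param ranking A `ranking_result`.
#' @param n Rank cutoffs (default `c(1, 10, 100)`).
#' @return Tibble (`n`, `hits`), non-decreasing in `n`.
#' @export
hits_at_n <- function(ranking, n = c(1L, 10L, 100L)) {
  pos <- ranking[ranking$label == 1, ]
  if (nrow(pos) == 0) stop("no positive associations in ranking",
                           call. = FALSE)
  tibble::tibble(n = as.integer(n),
                 hits = vapply(n, function(k) mean(pos$rank <= k),
                               numeric(1)))
}

#' Summarize a ranking into an evaluation report
#'
#' Bundles the macro-averaged ROC curve and area, the per-disease areas with
#' their spread, and recall at ranks 1, 10 and 100. When the ranking spans
#' cross-validation folds (a `fold` column), the area interval is the
#' min-max over folds of the fold-mean per-disease area.
#'
#' @param ranking A `ranking_result`, optionally with a `fold` column.
#' @param hits_n Rank cutoffs for recall.
#' @return An `eval_report` list: `rocauc` (mean per-disease area),
#'   `rocauc_interval`, `auc_macro`, `curve`, `per_disease`, `hits`.
#' @export
evaluate_ranking <- function(ranking, hits_n = c(1L, 10L, 100L)) {
  roc <- roc_curve_macro(ranking)
  if ("fold" %in% names(ranking)) {
    fold_means <- ranking |>
      dplyr::distinct(.data$disease, .data$fold) |>
      dplyr::inner_join(roc$per_disease, by = "disease") |>
      dplyr::group_by(.data$fold) |>
      dplyr::summarise(auc = mean(.data$auc), .groups = "drop")
    interval <- range(fold_means$auc)
  } else {
    interval <- range(roc$per_disease$auc)
  }
  structure(list(rocauc = mean(roc$per_disease$auc),
                 rocauc_interval = interval,
                 auc_macro = roc$auc_macro,
                 curve = roc$curve,
                 per_disease = roc$per_disease,
                 hits = hits_at_n(ranking, hits_n)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> mean per-disease ROCAUC %.3f (%.3f-%.3f), macro-curve area %.3f\n",
              x$rocauc, x$rocauc_interval[1], x$rocauc_interval[2],
              x$auc_macro))
  for (i in seq_len(nrow(x$hits))) {
    cat(sprintf("  Hits@%-3d %.3f\n", x$hits$n[i], x$hits$hits[i]))
  }
  invisible(x)
}

#' @export
glance.eval_report <- function(x, ...) {
  out <- tibble::tibble(rocauc = x$rocauc,
                        rocauc_min = x$rocauc_interval[1],
                        rocauc_max = x$rocauc_interval[2],
                        auc_macro = x$auc_macro)
  for (i in seq_len(nrow(x$hits))) {
    out[[paste0("hits_at_", x$hits$n[i])]] <- x$hits$hits[i]
  }
  out
}

#' @export
autoplot.eval_report <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::geom_line(color = "#2166ac") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("Macro-averaged ROC (area %.3f)",
                                  object$auc_macro)) +
    ggplot2::theme_minimal()
}

#' Write an evaluation report to disk
#'
#' The scalar summaries (areas, interval, recalls) go to JSON; the
#' macro-averaged curve goes to a TSV alongside.
#'
#' @param report An `eval_report`.
#' @param json_path Output path for the JSON summary.
#' @param curve_path Optional output path for the curve TSV.
#' @return `json_path`, invisibly.
#' @export
write_eval_report <- function(report, json_path, curve_path = NULL) {
  stopifnot(inherits(report, "eval_report"))
  summary <- list(rocauc = report$rocauc,
                  rocauc_min = report$rocauc_interval[1],
                  rocauc_max = report$rocauc_interval[2],
                  auc_macro = report$auc_macro,
                  hits_at = stats::setNames(as.list(report$hits$hits),
                                            paste0("n", report$hits$n)))
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(curve_path)) {
    utils::write.table(report$curve, curve_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(json_path)
}

#' Compare two models' true-positive rank distributions
#'
#' Two-sided Mann-Whitney U test on the ranks that two prediction models
#' assign to the same set of true gene-disease associations; a difference is
#' called significant at P < 0.05. Exact for small samples without ties, via
#' [stats::wilcox.test()].
#'
#' @param ranks_a,ranks_b Either tibbles (`gene`, `disease`, `rank`) over an
#'   identical association set, or bare numeric rank vectors of equal
#'   meaning.
#' @return Tibble (`statistic`, `p_value`, `significant`).
#' @export
compare_models <- function(ranks_a, ranks_b) {
  if (is.data.frame(ranks_a) || is.data.frame(ranks_b)) {
    stopifnot(is.data.frame(ranks_a), is.data.frame(ranks_b),
              all(c("gene", "disease", "rank") %in% names(ranks_a)),
              all(c("gene", "disease", "rank") %in% names(ranks_b)))
    key_a <- sort(paste(ranks_a$gene, ranks_a$disease, sep = "\r"),
                  method = "radix")
    key_b <- sort(paste(ranks_b$gene, ranks_b$disease, sep = "\r"),
                  method = "radix")
    if (!identical(key_a, key_b)) {
      stop("the two models were not evaluated on identical association sets",
           call. = FALSE)
    }
    ra <- ranks_a$rank
    rb <- ranks_b$rank
  } else {
    if (length(ranks_a) != length(ranks_b)) {
      stop("rank vectors must cover the same associations", call. = FALSE)
    }
    ra <- ranks_a
    rb <- ranks_b
  }
  wt <- suppressWarnings(stats::wilcox.test(ra, rb,
                                            alternative = "two.sided"))
  tibble::tibble(statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 significant = wt$p.value < 0.05)
}
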