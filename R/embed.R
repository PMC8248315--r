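#' Skip-gram embedding configuration
#'
#' Defaults follow the corpus-training regime for walk sentences: context
#' window of 10 tokens, minimum token frequency 1 (so every node and edge
#' label receives a vector), 200-dimensional vectors and 20 training
#' iterations, with skip-gram negative sampling (5 negatives).
#'
#' @param dim Embedding dimensionality (default 200).
#' @param window Context window size in tokens (default 10).
#' @param min_count Minimum token frequency for inclusion (default 1).
#' @param epochs Training iterations over the corpus (default 20).
#' @param negative Negative samples per positive pair (default 5).
#' @param alpha Initial learning rate, linearly decayed (default 0.025).
#' @param seed Integer RNG seed; training is single-threaded and
#'   deterministic for a fixed seed.
#' @return An `embed_config` list.
#' @export
embed_config <- function(dim = 200L, window = 10L, min_count = 1L,
                         epochs = 20L, negative = 5L, alpha = 0.025,
                         seed = 1L) {
  stopifnot(dim >= 1, window >= 1, epochs >= 1, min_count >= 1, negative >= 1)
  structure(list(dim = as.integer(dim), window = as.integer(window),
                 min_count = as.integer(min_count),
                 epochs = as.integer(epochs), negative = as.integer(negative),
                 alpha = alpha, seed = as.integer(seed)),
            class = "embed_config")
}

#' Train skip-gram embeddings on a walk corpus
#'
#' Learns one real vector per token (nodes and edge labels alike) with
#' skip-gram negative sampling. Tokens rarer than `min_count` are removed
#' from the sentences before training, exactly as word2vec-style vocabulary
#' pruning does.
#'
#' @param corpus A `walk_corpus` from [build_corpus()].
#' @param config An [embed_config()].
#' @return An `embedding_table`: numeric matrix (tokens x dim) with token
#'   rownames and attributes `config` and `corpus_fingerprint`.
#' @export
train_embeddings <- function(corpus, config = embed_config()) {
  stopifnot(inherits(corpus, "walk_corpus"), inherits(config, "embed_config"))
  if (length(corpus$sentences) == 0) {
    stop("cannot train embeddings on an empty corpus", call. = FALSE)
  }
  keep <- corpus$counts >= config$min_count & corpus$counts > 0
  if (!any(keep)) stop("no token reaches min_count", call. = FALSE)
  # re-index the kept vocabulary densely for the trainer
  new_id <- cumsum(keep) - 1L          # 0-based ids for kept tokens
  sentences <- lapply(corpus$sentences, function(ids) {
    ids <- ids[keep[ids + 1L]]
    new_id[ids + 1L]
  })
  sentences <- sentences[lengths(sentences) > 0]
  vocab <- corpus$vocab[keep]
  counts <- corpus$counts[keep]
  mat <- cpp_train_sgns(sentences, as.numeric(counts), config$dim,
                        config$window, config$epochs, config$negative,
                        config$alpha, as.double(config$seed))
  rownames(mat) <- vocab
  stopifnot(all(is.finite(mat)))
  structure(mat,
            config = config,
            corpus_fingerprint = sprintf("%d sentences / %d tokens",
                                         length(corpus$sentences),
                                         sum(corpus$counts)),
            class = c("embedding_table", "matrix", "array"))
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table> %d tokens x %d dimensions\n",
              nrow(x), ncol(x)))
  invisible(x)
}

#' Look up embedding vectors for a set of identifiers
#'
#' Rows are returned in input order. Identifiers without a vector are either
#' dropped with a warning (`missing = "drop"`) or raise an error listing
#' them (`missing = "fail"`).
#'
#' @param table An `embedding_table`.
#' @param ids Character vector of token identifiers.
#' @param missing `"drop"` or `"fail"`.
#' @return Numeric matrix with one row per found identifier.
#' @export
lookup_embeddings <- function(table, ids, missing = c("drop", "fail")) {
  missing <- match.arg(missing)
  absent <- setdiff(ids, rownames(table))
  if (length(absent) > 0) {
    if (missing == "fail") {
      stop("identifiers without embeddings: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    warning("dropping ", length(absent), " identifier(s) without embeddings",
            call. = FALSE)
    ids <- ids[ids %in% rownames(table)]
  }
  out <- unclass(table)[ids, , drop = FALSE]
  attr(out, "config") <- NULL
  attr(out, "corpus_fingerprint") <- NULL
  out
}

#' Write / read an embedding table in word2vec text format
#'
#' Header line `vocab_size dim`, then one token per line followed by its
#' vector components — the interchange format external embedding tools use.
#'
#' @param table An `embedding_table`.
#' @param path Output file.
#' @return `write_embeddings` returns `path` invisibly; `read_embeddings`
#'   returns an `embedding_table` (without training metadata).
#' @export
write_embeddings <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(table), ncol(table)), con)
  body <- vapply(seq_len(nrow(table)), function(i) {
    paste(rownames(table)[i],
          paste(formatC(table[i, ], format = "g", digits = 8),
                collapse = " "))
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(lines[1], " ", fixed = TRUE)[[1]])
  parts <- strsplit(lines[-1], " ", fixed = TRUE)
  stopifnot(length(parts) == hdr[1])
  mat <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1])))
  rownames(mat) <- vapply(parts, `[[`, "", 1)
  stopifnot(ncol(mat) == hdr[2])
  structure(mat, class = c("embedding_table", "matrix", "array"))
}
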