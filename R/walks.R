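#' Random-walk configuration
#'
#' Defaults follow the walk regimes used for ontology-plus-annotation graphs:
#' 80 walks per node of 20 edge traversals each; when protein-protein
#' interaction edges are part of the graph the node degree is much higher, so
#' the regime switches to 200 walks of 30 steps.
#'
#' @param walks_per_node Walks started from every node (default 80; 200 in
#'   the interaction regime).
#' @param steps Edge traversals per walk (default 20; 30 in the interaction
#'   regime). A sentence therefore holds up to `2 * steps + 1` tokens.
#' @param seed Integer RNG seed; one stream per start node is derived from
#'   (`seed`, node id) so corpora are reproducible.
#' @param ppi Use the interaction regime defaults.
#' @return A `walk_config` list.
#' @export
walk_config <- function(walks_per_node = NULL, steps = NULL, seed = 1L,
                        ppi = FALSE) {
  if (is.null(walks_per_node)) walks_per_node <- if (ppi) 200L else 80L
  if (is.null(steps)) steps <- if (ppi) 30L else 20L
  stopifnot(walks_per_node >= 1, steps >= 0)
  structure(list(walks_per_node = as.integer(walks_per_node),
                 steps = as.integer(steps), seed = as.integer(seed)),
            class = "walk_config")
}

#' Generate a single random walk
#'
#' Walks the graph as undirected, choosing the next node uniformly from the
#' undirected adjacency multiset, and emits edge labels between node tokens.
#' The walk stops early only at a node without neighbors, which can only be
#' the start node.
#'
#' @param g A `labeled_graph`.
#' @param start Start node identifier.
#' @param steps Number of edge traversals.
#' @param seed Integer RNG seed.
#' @return Character vector of alternating node and edge-label tokens.
#' @export
random_walk <- function(g, start, steps, seed = 1L) {
  stopifnot(inherits(g, "labeled_graph"))
  if (!start %in% g$nodes) {
    stop("start node not in graph: ", start, call. = FALSE)
  }
  gi <- graph_indices(g)
  walks <- cpp_generate_walks(length(gi$nodes), gi$src, gi$dst, gi$lab,
                              match(start, gi$nodes) - 1L,
                              1L, as.integer(steps), as.double(seed))
  vocab <- c(gi$nodes, gi$labels)
  vocab[walks[[1]] + 1L]
}

#' Build the walk-sentence corpus for a graph
#'
#' Starts `walks_per_node` walks from every node of the graph (isolated
#' nodes yield single-token sentences), so the corpus holds exactly
#' `walks_per_node * length(g$nodes)` sentences. Sentences interleave node
#' and edge-label tokens; both enter the skip-gram vocabulary.
#'
#' @param g A `labeled_graph`.
#' @param config A [walk_config()].
#' @return A `walk_corpus`: list with `sentences` (list of 0-based integer
#'   token-id vectors), `vocab` (token strings; node ids then edge labels)
#'   and `counts` (token frequencies).
#' @export
build_corpus <- function(g, config = walk_config()) {
  stopifnot(inherits(g, "labeled_graph"), inherits(config, "walk_config"))
  gi <- graph_indices(g)
  if (length(gi$nodes) == 0) {
    warning("build_corpus: empty graph, empty corpus", call. = FALSE)
    return(structure(list(sentences = list(), vocab = character(),
                          counts = integer(), config = config),
                     class = "walk_corpus"))
  }
  sentences <- cpp_generate_walks(length(gi$nodes), gi$src, gi$dst, gi$lab,
                                  seq_along(gi$nodes) - 1L,
                                  config$walks_per_node, config$steps,
                                  as.double(config$seed))
  vocab <- c(gi$nodes, gi$labels)
  counts <- tabulate(unlist(sentences, use.names = FALSE) + 1L,
                     nbins = length(vocab))
  structure(list(sentences = sentences, vocab = vocab, counts = counts,
                 config = config),
            class = "walk_corpus")
}

#' @export
print.walk_corpus <- function(x, ...) {
  cat(sprintf("<walk_corpus> %d sentences, %d vocabulary tokens\n",
              length(x$sentences), sum(x$counts > 0)))
  invisible(x)
}

#' Materialize corpus sentences as token strings
#'
#' @param corpus A `walk_corpus`.
#' @return Character vector, one space-separated sentence per element.
#' @export
corpus_sentences <- function(corpus) {
  stopifnot(inherits(corpus, "walk_corpus"))
  vapply(corpus$sentences,
         function(ids) paste(corpus$vocab[ids + 1L], collapse = " "),
         character(1))
}

#' Write / read a walk corpus as plain text
#'
#' One sentence per line, space-separated tokens — the format skip-gram
#' trainers consume.
#'
#' @param corpus A `walk_corpus`.
#' @param path Output file.
#' @return `write_corpus` returns `path` invisibly; `read_corpus` returns a
#'   `walk_corpus`.
#' @export
write_corpus <- function(corpus, path) {
  writeLines(corpus_sentences(corpus), path)
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  toks <- strsplit(lines, " ", fixed = TRUE)
  vocab <- unique(unlist(toks, use.names = FALSE))
  sentences <- lapply(toks, function(x) match(x, vocab) - 1L)
  counts <- tabulate(unlist(sentences, use.names = FALSE) + 1L,
                     nbins = length(vocab))
  structure(list(sentences = sentences, vocab = vocab, counts = counts,
                 config = NULL),
            class = "walk_corpus")
}
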