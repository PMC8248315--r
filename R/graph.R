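#' Labeled graphs over ontology classes, genes and diseases
#'
#' A `labeled_graph` stores directed labeled triples
#' (`subject`, `predicate`, `object`) with set semantics (no duplicates, no
#' edge weights). Walks traverse the graph as undirected: an edge is listed
#' from both endpoints with the same (forward) label.
#'
#' @param triples Tibble with character columns `subject`, `predicate`,
#'   `object`.
#' @param nodes Optional extra node identifiers to include even when isolated.
#' @return A `labeled_graph`: list with elements `triples` (deduplicated
#'   tibble) and `nodes` (sorted character vector).
#' @export
labeled_graph <- function(triples = NULL, nodes = character()) {
  if (is.null(triples)) {
    triples <- tibble::tibble(subject = character(), predicate = character(),
                              object = character())
  }
  triples <- tibble::as_tibble(triples)
  stopifnot(all(c("subject", "predicate", "object") %in% names(triples)))
  triples <- dplyr::distinct(triples, .data$subject, .data$predicate,
                             .data$object)
  structure(list(triples = triples,
                 nodes = sort_c(unique(c(triples$subject, triples$object,
                                         nodes)))),
            class = "labeled_graph")
}

#' @export
print.labeled_graph <- function(x, ...) {
  cat(sprintf("<labeled_graph> %d nodes, %d triples, %d edge labels\n",
              length(x$nodes), nrow(x$triples),
              length(unique(x$triples$predicate))))
  invisible(x)
}

# Separator used to compose quantifier-chain relation labels into one token.
CHAIN_SEP <- "."

compose_relations <- function(relations) paste(relations, collapse = CHAIN_SEP)

#' Transform one normalized axiom into graph triples
#'
#' Applies the axiom-to-triple rules:
#' * named subclass `A` of `B` with no quantifier chain ->
#'   one triple `<A, SubClassOf, B>`; equivalence likewise with
#'   `EquivalentTo`.
#' * a quantifier chain over relations `R0 ... Rm` ending in a class name or
#'   flat union/intersection `B1 ... Bn` -> one triple
#'   `<A, R0.R1...Rm, Bi>` per member, the chain composed into a single
#'   edge-label token (separator `.`). Existential, universal and
#'   cardinality quantifiers are treated identically, and equivalence with a
#'   complex right-hand side follows the same rule as subclass.
#'
#' @param kind `"subclass"` or `"equivalence"`.
#' @param subject Class name.
#' @param relations Character vector of chain relation names (may be empty).
#' @param filler_kind `"named"`, `"union"` or `"intersection"`.
#' @param fillers Character vector of filler class names.
#' @return Tibble of triples (`subject`, `predicate`, `object`).
#' @examples
#' transform_axiom("subclass", "feeding_behavior",
#'                 character(), "named", "behavior")
#' @export
transform_axiom <- function(kind, subject, relations, filler_kind, fillers) {
  if (length(relations) == 0 && filler_kind == "named") {
    pred <- if (kind == "subclass") "SubClassOf" else "EquivalentTo"
    return(tibble::tibble(subject = subject, predicate = pred,
                          object = fillers))
  }
  stopifnot(length(relations) >= 1)
  tibble::tibble(subject = subject,
                 predicate = compose_relations(relations),
                 object = fillers)
}

#' Transform every axiom in an axiom set into triples
#'
#' @param axioms An `axiom_set` from [parse_axioms()].
#' @return Tibble of deduplicated triples.
#' @export
transform_axioms <- function(axioms) {
  stopifnot(inherits(axioms, "axiom_set"))
  if (nrow(axioms) == 0) {
    return(tibble::tibble(subject = character(), predicate = character(),
                          object = character()))
  }
  purrr::pmap(list(axioms$kind, axioms$subject, axioms$relations,
                   axioms$filler_kind, axioms$fillers),
              function(kind, subject, relations, filler_kind, fillers) {
                transform_axiom(kind, subject, relations, filler_kind, fillers)
              }) |>
    dplyr::bind_rows() |>
    dplyr::distinct()
}

#' Add entity-class association edges to a graph
#'
#' Each association `(e, rel, c)` — e.g. a gene annotated with a function
#' class — becomes a direct triple `<e, rel, c>`; nodes are created on
#' demand.
#'
#' @param g A `labeled_graph`.
#' @param assocs Association tibble (`entity_id`, `relation`, `class_id`).
#' @return The enlarged `labeled_graph`.
#' @export
add_associations <- function(g, assocs) {
  stopifnot(inherits(g, "labeled_graph"))
  if (is.null(assocs) || nrow(assocs) == 0) return(g)
  new_triples <- tibble::tibble(subject = assocs$entity_id,
                                predicate = assocs$relation,
                                object = assocs$class_id)
  labeled_graph(dplyr::bind_rows(g$triples, new_triples), nodes = g$nodes)
}

#' Add protein-protein interaction edges to a graph
#'
#' Each interaction becomes a triple `<a, interacts-with, b>`. Since walks
#' traverse the graph as undirected, edge direction is immaterial and a pair
#' present in both orders collapses to one triple.
#'
#' @param g A `labeled_graph`.
#' @param interactions Tibble with columns `entity_a`, `entity_b`.
#' @param relation Edge label, default `"interacts-with"`.
#' @return The enlarged `labeled_graph`.
#' @export
add_interactions <- function(g, interactions, relation = "interacts-with") {
  stopifnot(inherits(g, "labeled_graph"))
  if (is.null(interactions) || nrow(interactions) == 0) return(g)
  a <- pmin(interactions$entity_a, interactions$entity_b)
  b <- pmax(interactions$entity_a, interactions$entity_b)
  new_triples <- tibble::tibble(subject = a, predicate = relation, object = b)
  labeled_graph(dplyr::bind_rows(g$triples, new_triples), nodes = g$nodes)
}

#' Build the full labeled graph from axioms, associations and interactions
#'
#' Unions the transformed ontology axioms with entity-class association
#' edges and optional interaction edges, deduplicated as a triple set.
#'
#' @param axioms An `axiom_set`.
#' @param assocs Optional association tibble.
#' @param interactions Optional interaction tibble.
#' @return A `labeled_graph`.
#' @export
build_graph <- function(axioms, assocs = NULL, interactions = NULL) {
  g <- labeled_graph(transform_axioms(axioms))
  g <- add_associations(g, assocs)
  g <- add_interactions(g, interactions)
  if (nrow(g$triples) == 0) {
    warning("build_graph: resulting graph has no edges", call. = FALSE)
  }
  g
}

#' Write / read a labeled graph as a 3-column TSV edge list
#'
#' @param g A `labeled_graph`.
#' @param path Output file.
#' @return `write_edgelist` returns `path` invisibly; `read_edgelist`
#'   returns a `labeled_graph`.
#' @export
write_edgelist <- function(g, path) {
  stopifnot(inherits(g, "labeled_graph"))
  utils::write.table(g$triples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_edgelist
#' @export
read_edgelist <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("subject", "predicate", "object"))
  labeled_graph(tibble::as_tibble(df))
}

# Integer-indexed view of a graph for the C++ walker: 0-based node and label
# ids plus the edge arrays.
graph_indices <- function(g) {
  nodes <- g$nodes
  labels <- sort_c(unique(g$triples$predicate))
  list(nodes = nodes, labels = labels,
       src = match(g$triples$subject, nodes) - 1L,
       dst = match(g$triples$object, nodes) - 1L,
       lab = match(g$triples$predicate, labels) - 1L)
}
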