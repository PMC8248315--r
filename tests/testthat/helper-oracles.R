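# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package implementation.

# Naive rule applier: builds each triple by string assembly, one explicit
# branch per transformation pattern.
oracle_transform <- function(kind, subject, relations, filler_kind, fillers) {
  out <- data.frame(subject = character(), predicate = character(),
                    object = character(), stringsAsFactors = FALSE)
  if (length(relations) == 0 && filler_kind == "named") {
    pred <- if (kind == "subclass") "SubClassOf" else "EquivalentTo"
    return(data.frame(subject = subject, predicate = pred, object = fillers[1],
                      stringsAsFactors = FALSE))
  }
  label <- relations[1]
  if (length(relations) > 1) {
    for (i in 2:length(relations)) label <- paste0(label, ".", relations[i])
  }
  for (b in fillers) {
    out <- rbind(out, data.frame(subject = subject, predicate = label,
                                 object = b, stringsAsFactors = FALSE))
  }
  out
}

# Random axiom within the supported grammar (chain length 0-3, filler named
# or flat boolean of 2-4 members).
random_axiom <- function(classes, rels) {
  kind <- sample(c("subclass", "equivalence"), 1)
  n_chain <- sample(0:3, 1)
  filler_kind <- if (n_chain == 0) "named" else
    sample(c("named", "union", "intersection"), 1)
  fillers <- if (filler_kind == "named") sample(classes, 1) else
    sample(classes, sample(2:4, 1))
  list(kind = kind,
       subject = sample(classes, 1),
       quantifiers = if (n_chain > 0)
         sample(c("existential", "universal", "cardinality"), n_chain,
                replace = TRUE) else character(),
       relations = if (n_chain > 0) sample(rels, n_chain, replace = TRUE)
         else character(),
       filler_kind = filler_kind,
       fillers = fillers)
}

# Verify every consecutive (node, label, node) triple of a sentence against
# the undirected edge set.
oracle_walk_valid <- function(tokens, triples) {
  if (length(tokens) == 1) return(TRUE)
  fwd <- paste(triples$subject, triples$predicate, triples$object)
  rev <- paste(triples$object, triples$predicate, triples$subject)
  edges <- c(fwd, rev)
  k <- (length(tokens) - 1) / 2
  for (i in seq_len(k)) {
    step <- paste(tokens[2 * i - 1], tokens[2 * i], tokens[2 * i + 1])
    if (!step %in% edges) return(FALSE)
  }
  TRUE
}

# ROCAUC by explicit positive-negative pair counting (ties get half credit).
oracle_auc_pairs <- function(score, label) {
  pos <- score[label == 1]
  neg <- score[label == 0]
  wins <- 0
  for (p in pos) for (q in neg) {
    if (p > q) wins <- wins + 1
    else if (p == q) wins <- wins + 0.5
  }
  wins / (length(pos) * length(neg))
}

# A small graph shared by walker tests: star plus a tail.
toy_graph <- function() {
  labeled_graph(tibble::tibble(
    subject = c("hub", "hub", "hub", "hub", "t1"),
    predicate = c("r", "r", "r", "s", "s"),
    object = c("a", "b", "c", "t1", "t2")))
}

small_bundle <- function(seed = 5) {
  generate_benchmark(synth_config(n_classes = 50, n_cross_axioms = 30,
                                  n_genes = 60, n_diseases = 10,
                                  genes_per_disease = 2,
                                  annotations_per_entity = 4, seed = seed))
}
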