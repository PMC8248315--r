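---
title: "Methods: ontology-graph embeddings and learning-to-rank gene prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ontology-graph embeddings and learning-to-rank gene prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Phenotype-based gene prioritization ranks candidate genes for a disease by
comparing what is known about the genes (mutant phenotypes in model
organisms, functions of gene products, anatomical sites of expression) with
what is known about the disease (its abnormal phenotypes). Ontologies make
this comparison possible across data types: phenotype classes are formally
*defined* in terms of function and anatomy classes (EQ-style definitions,
e.g. a visual-impairment phenotype defined as decreased visual perception),
so a gene annotated only with a function class can still be related to a
disease annotated only with phenotype classes — but only if those defining
axioms are actually used. `ontorank` implements a graph-based embedding
method that exploits such axioms, plus the supervised ranking model and the
evaluation protocol around it.

## From axioms to a labeled graph

Axioms are normalized to three patterns and converted to triples:

| axiom shape                               | triples                                  |
|-------------------------------------------|------------------------------------------|
| `A SubClassOf B` (named)                  | `<A, SubClassOf, B>`                     |
| `A EquivalentTo B` (named)                | `<A, EquivalentTo, B>`                   |
| `A ⊑/≡ Q R0 ... Q Rm (B1 ⊔/⊓ ... ⊔/⊓ Bn)` | `<A, R0.R1...Rm, Bi>` for each member    |

`Q` is any quantifier (existential, universal, cardinality); all three map
to identical edges, and equivalence with a complex right-hand side follows
the same rule as subclass. A quantifier chain is composed into one edge
label joined with `.`. Boolean fillers must be flat (class names only);
nested combinations and boolean fillers without a quantifier chain match no
rule and are counted and reported as skipped, never silently dropped.

Entity annotations become direct edges `<gene, has-function, GO-class>`,
`<gene, expressed-in, anatomy-class>`, `<disease, has-phenotype,
phenotype-class>`, and protein interactions become `<a, interacts-with, b>`
edges. Gold-standard gene–disease pairs are **never** added to the graph;
they are training labels only, which keeps the embedding stage blind to the
supervision signal.

Standard upstream filters are provided: annotation records with evidence
codes `IEA`/`ND` are excluded; a gene counts as expressed in a tissue at
`TPM >= 4.0` (inclusive — the threshold itself is called a cutoff, so the
boundary value passes); interactions require a confidence of at least 700
(inclusive); ortholog mapping is a plain table join that drops and counts
unmapped entities. All filters are idempotent.

## Walks and embeddings

From every node we start `walks_per_node` uniform random walks of `steps`
edge traversals, treating the graph as undirected and emitting edge labels
between node tokens (a walk of `k` steps is a sentence of `2k + 1` tokens).
Defaults are 80 walks of 20 steps; when interaction edges are present the
regime switches to 200 walks of 30 steps to compensate for the higher node
degree. Reverse traversal emits the forward label (no inverse marker), walks
may backtrack (no second-order biasing), and a self-loop is an ordinary
neighbor. One RNG stream per start node is derived from (seed, node id), so
corpora are byte-identical across runs and independent of scheduling.

The corpus is fed to skip-gram with negative sampling (5 negatives,
unigram^0.75 noise distribution, dynamic window shrinking, linear
learning-rate decay from 0.025) with window 10, `min_count` 1 and 20 epochs
as defaults, producing one vector per node *and* per edge label; only node
vectors feed the ranker. Training is single-threaded and deterministic per
seed. There is no frequency subsampling: walk corpora have no Zipf-like head
of stop words, so the word2vec subsampling heuristic has nothing to remove.

## The ranking model

A (gene, disease) pair is scored by two independent feed-forward towers
(hidden widths 256 then 50; each dense layer followed by 20% dropout and a
leaky rectifier), the inner product of the two 50-dimensional outputs, and a
sigmoid. Training minimizes binary cross-entropy with Adam (learning rate
1e-4, batch size 128), sampling 20 negative pairs per positive once per fold
(fixed and seeded, not resampled across epochs, for reproducibility).
Evaluation uses 10-fold cross-validation split **by disease**, never by
association pair: each disease is tested exactly once, and within a fold the
non-test diseases are split 90:10 into training and validation (also by
disease, for consistency with the outer split).

Three numerical choices deserve explanation, because the obvious
alternatives fail at benchmark scale:

* **Model selection on validation ranking AUC, not validation loss.** With
  20 negatives per positive, validation cross-entropy keeps improving while
  the model drifts from an early similarity-based solution into memorizing
  which genes were training positives — a solution that ranks *worse* than
  chance on held-out diseases, because training positives crowd the top of
  every candidate list. Mean per-disease validation AUC peaks exactly at the
  generalizing epochs, so the best epoch is chosen (and early stopping with
  patience 10 is triggered) on that quantity. The validation loss is still
  recorded in the training history.
* **Shared tower initialization, best of five draws.** Both towers start
  from the same random weights (they diverge freely during training). With
  identical towers the inner-product head is a Johnson–Lindenstrauss-style
  similarity kernel from the first forward pass, which starts optimization
  at, rather than far from, the similarity solution that generalizes across
  diseases. Kernel fidelity varies noticeably between random draws, so five
  initializations are screened per fold by their epoch-0 validation ranking
  AUC (forward passes only) and the best is trained.
* **Epoch 0 is a model-selection candidate.** With few training diseases
  (tens rather than thousands), gradient training can degrade cross-disease
  generalization from the very first epoch; the per-fold validation AUC
  decides whether any amount of training improved on the initialization
  kernel. With many diseases this candidate is simply outvoted.
* **Leaky slope 0.3** (the Keras `LeakyReLU` default, which the original
  implementations of this model family use). A gentle negative slope also
  preserves more of the embedding geometry through the towers than the
  steeper 0.01 variant.
* **Learning rate 1e-4.** At the Keras-default 1e-3 the first epochs already
  leave the similarity regime; at 1e-4 gradient training measurably improves
  on the initialization kernel before the slow drift toward memorization,
  which the validation-AUC early stopping then cuts off.
* **L2-normalized inputs.** Skip-gram vector norms track token frequency,
  not biology; only the direction carries the similarity signal, so
  embedding rows are normalized before entering the towers, identically at
  training and scoring time.

Scores are strictly inside (0, 1); evaluation-mode scoring (dropout off) is
deterministic; and the score is *not* symmetric in its arguments — the
towers are independent, so `score(g, d)` and `score(d, g)` differ in
general.

## Evaluation

For each test disease, all genes of the candidate universe are ranked by
descending score, ties broken by a stable ordering on gene identifier. Two
area summaries are reported: the mean per-disease ROCAUC (each disease's
area computed through the rank-sum identity `AUC = U / (n+ n-)`, tied scores
receiving half credit), and the macro-averaged curve obtained by averaging
per-disease TPR/FPR at each rank of the shared universe and applying the
trapezoid rule. Cross-validation intervals are reported as the min–max over
folds of the fold-mean per-disease area. Hits@n (n = 1, 10, 100) is the
fraction of true associations whose gene ranks within the top n. Two models
evaluated on the same association set are compared with a two-sided
Mann–Whitney U test on the ranks they assign to true positives, significant
at P < 0.05.

## The synthetic benchmark

`generate_benchmark()` builds the entire input set with planted,
axiom-mediated signal:

* three subclass trees (phenotype-, function- and anatomy-like; 200 classes
  each, branching factor 3);
* 120 cross-ontology axioms defining phenotype classes in terms of
  function/anatomy classes, cycling through four shapes (existential over a
  union, a two-relation existential chain, existential over an
  intersection, plain existential) so every transformation rule is
  exercised;
* 40 diseases annotated with 6 phenotype classes drawn from the
  cross-defined set; 300 genes (3 causal genes per disease, disjoint across
  diseases) annotated with 6 function/anatomy classes.

For a causal gene, each annotation slot is filled with a class that the
axioms link to one of its disease's phenotype classes with probability
`signal` (default 0.8), otherwise at random; `noise` (default 0.2) appends
that fraction of additional random annotations to every entity. At
`signal = 1, noise = 0` every gold pair is connected by a length-3 path
(gene → annotation class → defining axiom → phenotype ← disease), which is
asserted structurally in the tests. At `signal = 0` the gold standard is
independent of the graph and the pipeline must score at chance. Optionally,
interaction edges are planted between co-causal genes (confidence 700–1000)
among 4x as many random decoy edges (confidence 150–1000).

What the generator does *not* emulate: realistic ontology sizes and degree
distributions, annotation sparsity and bias, shared causal genes between
diseases, and the thousands-of-diseases regime in which the supervised model
has enough signal to improve substantially on its initialization kernel.
Passing the planted benchmark therefore demonstrates that the pipeline
recovers axiom-mediated structure end-to-end and that its components are
correct — not that real-data performance numbers transfer.

## Validation problem sizes

The bundled end-to-end validation (tests and `scripts/acceptance.R`) runs
the default generator (600 classes, 300 genes, 40 diseases; about 940 graph
nodes), the default walk regime (80 walks x 20 steps, about 75,000
sentences), and 100-dimensional embeddings trained for 5 epochs — on this
small, dense graph the skip-gram geometry is already stable after a few
epochs (planted-pair cosine separation stops improving), so the package's
validation runs use 5 epochs and keep the paper-scale default of 20 for real
corpora. Three seeds are averaged for the recovery run; the shuffled-label
control reuses the first run's embeddings, which is valid because the graph
and walks never see the gold labels. Signal monotonicity (AUC non-decreasing
over signal 0, 0.5, 1) is checked on a reduced generator (60 classes per
ontology, 80 genes, 12 diseases, 30 walks, 50 dimensions) to keep the full
suite fast.

## Known limitations

* The axiom normal form is deliberately restricted to the patterns the
  transformation consumes; OBO genus-differentia definitions that mix a
  genus with relational differentia are skipped (and counted).
* No OWL reasoning: asserted axioms only, no transitive closure over the
  subclass hierarchy.
* The method is transductive: all diseases and genes must be nodes of the
  graph before embedding; scoring a new entity requires re-walking and
  re-embedding.
* The two-tower model only demonstrably improves on its initialization
  kernel when many diseases are available for training; at small scale the
  validation-AUC selection falls back to the kernel.
* Embedding training is single-threaded by design (bit-for-bit
  reproducibility); corpus generation is the cheap stage, skip-gram the
  expensive one.
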