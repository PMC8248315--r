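#' Configuration for the synthetic planted benchmark
#'
#' Generates three toy class hierarchies (phenotype-, function- and
#' anatomy-like), cross-ontology axioms that define phenotype classes in
#' terms of function/anatomy classes (the EQ-definition mechanism that links
#' phenotype ontologies to GO/UBERON), gene and disease annotations, and a
#' gold standard of causal gene-disease pairs whose signal travels only
#' through those axioms: at `signal = 1`, every causal gene shares an
#' axiom-linked class with its disease's phenotype classes, placing gene and
#' disease within three edges of each other in the graph.
#'
#' @param n_classes Classes per ontology (default 200).
#' @param branching Branching factor of each subclass tree (default 3).
#' @param n_cross_axioms Phenotype classes given cross-ontology defining
#'   axioms (default 120).
#' @param n_genes,n_diseases Entity counts (defaults 300 and 40).
#' @param annotations_per_entity Annotation classes per gene/disease
#'   (default 6).
#' @param genes_per_disease Causal genes per disease (default 3).
#' @param signal Fraction of a causal gene's annotation slots filled with a
#'   class axiom-linked to its disease's phenotype classes (default 0.8).
#' @param noise Fraction of additional random annotations appended per
#'   entity (default 0.2).
#' @param interactions Plant `interacts-with` edges between co-causal genes
#'   plus random decoy edges (default `FALSE`).
#' @param seed Integer RNG seed; the whole bundle is deterministic per seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_classes = 200L, branching = 3L,
                         n_cross_axioms = 120L, n_genes = 300L,
                         n_diseases = 40L, annotations_per_entity = 6L,
                         genes_per_disease = 3L, signal = 0.8, noise = 0.2,
                         interactions = FALSE, seed = 1L) {
  stopifnot(signal >= 0, signal <= 1, noise >= 0, noise <= 1,
            n_classes >= 2, n_genes >= 1, n_diseases >= 1)
  if (n_cross_axioms > n_classes - 1) {
    stop("infeasible config: n_cross_axioms exceeds available phenotype classes",
         call. = FALSE)
  }
  if (annotations_per_entity > n_cross_axioms) {
    stop("infeasible config: annotations_per_entity exceeds n_cross_axioms",
         call. = FALSE)
  }
  if (genes_per_disease * n_diseases > n_genes) {
    stop("infeasible config: not enough genes for disjoint causal sets",
         call. = FALSE)
  }
  structure(list(n_classes = as.integer(n_classes),
                 branching = as.integer(branching),
                 n_cross_axioms = as.integer(n_cross_axioms),
                 n_genes = as.integer(n_genes),
                 n_diseases = as.integer(n_diseases),
                 annotations_per_entity = as.integer(annotations_per_entity),
                 genes_per_disease = as.integer(genes_per_disease),
                 signal = signal, noise = noise,
                 interactions = interactions, seed = as.integer(seed)),
            class = "synth_config")
}

synth_ids <- function(prefix, n) sprintf("%s:%04d", prefix, seq_len(n))

# Subclass tree over ids with the given branching factor: node i's parent is
# floor((i - 2) / b) + 1; node 1 is the root.
tree_axioms <- function(ids, branching) {
  if (length(ids) < 2) return(empty_axiom_tbl())
  i <- 2:length(ids)
  dplyr::bind_rows(purrr::map(i, function(j) {
    axiom_row("subclass", ids[j], character(), character(), "named",
              ids[(j - 2) %/% branching + 1])
  }))
}

#' Generate a synthetic benchmark bundle
#'
#' See [synth_config()] for the construction. The returned bundle carries
#' everything the pipeline consumes: a normalized axiom set, entity-class
#' associations, optional interaction edges, the gold gene-disease pairs and
#' truth metadata recording which classes carry the planted signal.
#'
#' @param config A [synth_config()].
#' @return A `synth_bundle` list: `axioms`, `associations`, `interactions`,
#'   `gold`, `truth`, `genes`, `diseases`, `config`.
#' @export
generate_benchmark <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, {
    ph <- synth_ids("PH", config$n_classes)
    fn <- synth_ids("FN", config$n_classes)
    an <- synth_ids("AN", config$n_classes)
    genes <- synth_ids("G", config$n_genes)
    diseases <- sprintf("D:%03d", seq_len(config$n_diseases))

    axioms <- dplyr::bind_rows(tree_axioms(ph, config$branching),
                               tree_axioms(fn, config$branching),
                               tree_axioms(an, config$branching))

    # cross-ontology defining axioms: phenotype -> function/anatomy classes
    cross_ph <- sample(ph[-1], config$n_cross_axioms)
    truth <- list()
    cross_rows <- list()
    for (i in seq_along(cross_ph)) {
      p <- cross_ph[i]
      form <- (i - 1) %% 4 + 1
      if (form == 1) {                     # P [= E has-part.(F u A)
        f <- sample(fn, 1)
        a <- sample(an, 1)
        cross_rows[[i]] <- axiom_row("subclass", p, "existential",
                                     "has-part", "union", c(f, a))
        truth[[i]] <- tibble::tibble(pheno = p, linked = c(f, a),
                                     relation = c("has-function",
                                                  "expressed-in"))
      } else if (form == 2) {              # P == E has-part.E part-of.F
        f <- sample(fn, 1)
        cross_rows[[i]] <- axiom_row("equivalence", p,
                                     c("existential", "existential"),
                                     c("has-part", "part-of"), "named", f)
        truth[[i]] <- tibble::tibble(pheno = p, linked = f,
                                     relation = "has-function")
      } else if (form == 3) {              # P [= E has-part.(F1 n F2)
        f <- sample(fn, 2)
        cross_rows[[i]] <- axiom_row("subclass", p, "existential",
                                     "has-part", "intersection", f)
        truth[[i]] <- tibble::tibble(pheno = p, linked = f,
                                     relation = "has-function")
      } else {                             # P [= E has-part.A
        a <- sample(an, 1)
        cross_rows[[i]] <- axiom_row("subclass", p, "existential",
                                     "has-part", "named", a)
        truth[[i]] <- tibble::tibble(pheno = p, linked = a,
                                     relation = "expressed-in")
      }
    }
    axioms <- dplyr::bind_rows(axioms, dplyr::bind_rows(cross_rows))
    truth <- dplyr::bind_rows(truth)

    # gold standard: disjoint causal gene sets per disease
    causal <- sample(genes, config$genes_per_disease * config$n_diseases)
    gold <- tibble::tibble(
      gene = causal,
      disease = rep(diseases, each = config$genes_per_disease))

    m <- config$annotations_per_entity
    n_extra <- round(config$noise * m)
    # background/noise gene annotations are drawn from the same axiom-linked
    # class pool the planted annotations use, so causal and background genes
    # have identical annotation marginals: the only planted signal is the
    # disease-SPECIFIC match between a gene's classes and the axioms defining
    # its own disease's phenotype classes. (Drawing background annotations
    # uniformly over all classes instead makes causal genes generically
    # closer to every disease and biases label-shuffled controls above 0.5.)
    linked_pool <- dplyr::distinct(truth[, c("relation", "linked")])
    random_gene_annotation <- function(k) {
      pick <- linked_pool[sample.int(nrow(linked_pool), k, replace = TRUE), ]
      tibble::tibble(relation = pick$relation, class_id = pick$linked)
    }

    # disease annotations: a signature of cross-defined phenotype classes,
    # plus noise extras drawn from the whole phenotype ontology
    signature <- stats::setNames(
      purrr::map(diseases, function(d) sample(cross_ph, m)), diseases)
    disease_assoc <- purrr::map_dfr(diseases, function(d) {
      cls <- c(signature[[d]],
               if (n_extra > 0) sample(ph, n_extra, replace = TRUE))
      tibble::tibble(entity_id = d, relation = "has-phenotype",
                     class_id = cls, source = "synthetic")
    })

    # gene annotations: causal genes fill each slot with an axiom-linked
    # class of the matching signature phenotype with probability `signal`
    gene_assoc <- purrr::map_dfr(genes, function(g) {
      d <- gold$disease[match(g, gold$gene)]
      rows <- if (!is.na(d)) {
        purrr::map_dfr(seq_len(m), function(slot) {
          if (stats::runif(1) < config$signal) {
            links <- truth[truth$pheno == signature[[d]][slot], ]
            pick <- links[sample.int(nrow(links), 1), ]
            tibble::tibble(relation = pick$relation, class_id = pick$linked)
          } else {
            random_gene_annotation(1)
          }
        })
      } else {
        random_gene_annotation(m)
      }
      if (n_extra > 0) rows <- dplyr::bind_rows(rows,
                                                random_gene_annotation(n_extra))
      tibble::tibble(entity_id = g, relation = rows$relation,
                     class_id = rows$class_id, source = "synthetic")
    })

    associations <- dplyr::bind_rows(disease_assoc, gene_assoc) |>
      dplyr::distinct(.data$entity_id, .data$relation, .data$class_id,
                      .keep_all = TRUE)

    interactions <- NULL
    if (isTRUE(config$interactions)) {
      planted <- gold |>
        dplyr::group_by(.data$disease) |>
        dplyr::reframe(as.data.frame(t(utils::combn(sort(.data$gene, method = "radix"), 2)))) |>
        dplyr::transmute(entity_a = .data$V1, entity_b = .data$V2,
                         confidence = sample(700:1000, dplyr::n(),
                                             replace = TRUE))
      n_decoy <- nrow(planted) * 4
      decoy <- tibble::tibble(entity_a = sample(genes, n_decoy, replace = TRUE),
                              entity_b = sample(genes, n_decoy, replace = TRUE),
                              confidence = sample(150:1000, n_decoy,
                                                  replace = TRUE))
      interactions <- filter_interactions(
        dplyr::bind_rows(planted, decoy[decoy$entity_a != decoy$entity_b, ]))
    }

    structure(list(axioms = new_axiom_set(axioms),
                   associations = associations,
                   interactions = interactions,
                   gold = gold, truth = truth,
                   genes = genes, diseases = diseases,
                   config = config),
              class = "synth_bundle")
  })
}

#' @export
print.synth_bundle <- function(x, ...) {
  cat(sprintf(paste0("<synth_bundle> %d axioms, %d associations, %d gold ",
                     "pairs, %d genes, %d diseases%s\n"),
              nrow(x$axioms), nrow(x$associations), nrow(x$gold),
              length(x$genes), length(x$diseases),
              if (is.null(x$interactions)) "" else
                sprintf(", %d interactions", nrow(x$interactions))))
  invisible(x)
}

#' Generate a synthetic gene-by-tissue TPM matrix
#'
#' Emulates a tissue-expression profile input for [threshold_expression()]:
#' a configurable fraction of cells carries expression at or above 4.0
#' transcripts per million; tissue columns are named by anatomy classes of
#' the bundle's anatomy-like ontology.
#'
#' @param config A [synth_config()].
#' @param fraction Fraction of (gene, tissue) cells called expressed
#'   (default 0.3).
#' @param n_tissues Number of tissue columns (default 10).
#' @return Numeric matrix, genes in rows, anatomy-class tissue ids in
#'   columns.
#' @export
generate_expression <- function(config = synth_config(), fraction = 0.3,
                                n_tissues = 10L) {
  stopifnot(fraction >= 0, fraction <= 1)
  withr::with_seed(config$seed + 211L, {
    genes <- synth_ids("G", config$n_genes)
    tissues <- synth_ids("AN", config$n_classes)[seq_len(n_tissues)]
    expressed <- matrix(stats::runif(length(genes) * n_tissues) < fraction,
                        length(genes), n_tissues)
    tpm <- matrix(stats::runif(length(genes) * n_tissues, 0, 3.99),
                  length(genes), n_tissues)
    tpm[expressed] <- stats::runif(sum(expressed), 4, 100)
    dimnames(tpm) <- list(genes, tissues)
    tpm
  })
}

#' Write a synthetic bundle to a fixture directory
#'
#' Writes the same plain-text formats the real pipeline reads: tsv_simple
#' axioms, an association TSV, an interaction TSV (when present) and a gold
#' TSV. Identical seeds produce byte-identical files.
#'
#' @param bundle A `synth_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synth_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  serialize_axioms(bundle$axioms, file.path(dir, "axioms.tsv"))
  utils::write.table(bundle$associations, file.path(dir, "associations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$interactions)) {
    utils::write.table(bundle$interactions, file.path(dir, "interactions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(bundle$gold, file.path(dir, "gold.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
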