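#' Filter functional annotations by evidence code
#'
#' Drops annotations whose evidence code marks them as inferred from
#' electronic annotation (`IEA`) or as having no biological data (`ND`), and
#' emits the remainder as `has-function` associations. The filter is
#' idempotent and never invents rows.
#'
#' @param records A data frame with at least the columns `entity_id`,
#'   `class_id` and `evidence`.
#' @param exclude Evidence codes to drop (default `c("IEA", "ND")`).
#' @return A tibble of associations with columns `entity_id`, `relation`
#'   (`"has-function"`), `class_id`, `source`, deduplicated on
#'   (`entity_id`, `relation`, `class_id`).
#' @examples
#' go <- tibble::tibble(entity_id = "g1", class_id = c("GO:1", "GO:2"),
#'                      evidence = c("IEA", "IDA"))
#' filter_go_annotations(go)
#' @export
filter_go_annotations <- function(records, exclude = c("IEA", "ND")) {
  records <- tibble::as_tibble(records)
  missing_cols <- setdiff(c("entity_id", "class_id", "evidence"), names(records))
  if (length(missing_cols) > 0) {
    stop("annotation table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records |>
    dplyr::filter(!(.data$evidence %in% exclude)) |>
    dplyr::transmute(entity_id = .data$entity_id,
                     relation = "has-function",
                     class_id = .data$class_id,
                     source = paste0("evidence:", .data$evidence)) |>
    dplyr::distinct(.data$entity_id, .data$relation, .data$class_id,
                    .keep_all = TRUE)
}

#' Threshold a gene-by-tissue expression matrix into expressed-in associations
#'
#' A gene is called expressed in a tissue when its abundance reaches
#' `cutoff` transcripts per million (inclusive: TPM >= cutoff). Tissues
#' without an anatomy-class mapping are skipped with a message, mirroring the
#' exclusion of tissues absent from the anatomy ontology.
#'
#' @param tpm A numeric matrix or data frame, genes in rows (rownames or a
#'   `gene` first column), tissues in columns.
#' @param cutoff TPM threshold, default 4.0.
#' @param tissue_map Optional named character vector mapping tissue column
#'   names to anatomy class identifiers; unmapped tissues are dropped with a
#'   message. When `NULL`, tissue names are used as class identifiers.
#' @return A tibble of `expressed-in` associations
#'   (`entity_id`, `relation`, `class_id`, `source`).
#' @export
threshold_expression <- function(tpm, cutoff = 4.0, tissue_map = NULL) {
  if (is.data.frame(tpm)) {
    if (!is.numeric(tpm[[1]]) && is.character(tpm[[1]])) {
      genes <- tpm[[1]]
      tpm <- as.matrix(tpm[, -1, drop = FALSE])
      rownames(tpm) <- genes
    } else {
      tpm <- as.matrix(tpm)
    }
  }
  stopifnot(is.matrix(tpm), !is.null(rownames(tpm)), !is.null(colnames(tpm)))
  if (anyNA(tpm) || any(tpm < 0)) {
    stop("TPM values must be non-negative and non-missing", call. = FALSE)
  }
  tissues <- colnames(tpm)
  if (!is.null(tissue_map)) {
    unmapped <- setdiff(tissues, names(tissue_map))
    if (length(unmapped) > 0) {
      message("threshold_expression: skipping ", length(unmapped),
              " tissue(s) without anatomy mapping: ",
              paste(unmapped, collapse = ", "))
      tpm <- tpm[, setdiff(tissues, unmapped), drop = FALSE]
      tissues <- colnames(tpm)
    }
    class_ids <- unname(tissue_map[tissues])
  } else {
    class_ids <- tissues
  }
  hits <- which(tpm >= cutoff, arr.ind = TRUE)
  tibble::tibble(entity_id = rownames(tpm)[hits[, 1]],
                 relation = "expressed-in",
                 class_id = class_ids[hits[, 2]],
                 source = sprintf("tpm>=%g", cutoff)) |>
    dplyr::distinct(.data$entity_id, .data$relation, .data$class_id,
                    .keep_all = TRUE) |>
    dplyr::arrange(.data$entity_id, .data$class_id)
}

#' Filter scored protein-protein interactions by confidence
#'
#' Keeps interactions with a confidence of at least `cutoff` (inclusive) and
#' deduplicates them as unordered pairs. Self-interactions are retained (they
#' become harmless self-loops in the graph) but reported with a message.
#'
#' @param edges A data frame with columns `entity_a`, `entity_b`,
#'   `confidence` (integer scores, STRING-style 0-1000 scale).
#' @param cutoff Minimum confidence, default 700.
#' @return A tibble of interaction edges (`entity_a`, `entity_b`,
#'   `confidence`), one row per unordered pair with the maximum confidence
#'   seen for that pair.
#' @export
filter_interactions <- function(edges, cutoff = 700) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("entity_a", "entity_b", "confidence") %in% names(edges)))
  out <- edges |>
    dplyr::filter(.data$confidence >= cutoff) |>
    dplyr::mutate(a = pmin(.data$entity_a, .data$entity_b),
                  b = pmax(.data$entity_a, .data$entity_b)) |>
    dplyr::group_by(.data$a, .data$b) |>
    dplyr::summarise(confidence = max(.data$confidence), .groups = "drop") |>
    dplyr::transmute(entity_a = .data$a, entity_b = .data$b,
                     confidence = .data$confidence)
  n_self <- sum(out$entity_a == out$entity_b)
  if (n_self > 0) {
    message("filter_interactions: retaining ", n_self, " self-interaction(s)")
  }
  out
}

#' Rewrite association entity identifiers through an ortholog map
#'
#' Joins associations (e.g. mouse gene phenotype records) to an ortholog
#' table and rewrites the entity identifiers to the target species (e.g.
#' human). Associations whose entity has no ortholog are dropped and counted;
#' many-to-many pairs expand combinatorially and are then deduplicated.
#'
#' @param assocs Association tibble (`entity_id`, `relation`, `class_id`,
#'   optionally `source`).
#' @param ortholog_map A data frame with columns `source_id`, `target_id`.
#' @return A tibble of rewritten associations with attribute `n_dropped`,
#'   the number of input associations lost to unmapped entities.
#' @export
map_orthologs <- function(assocs, ortholog_map) {
  assocs <- tibble::as_tibble(assocs)
  ortholog_map <- tibble::as_tibble(ortholog_map)
  stopifnot(all(c("entity_id", "relation", "class_id") %in% names(assocs)),
            all(c("source_id", "target_id") %in% names(ortholog_map)))
  if (!"source" %in% names(assocs)) assocs$source <- NA_character_
  joined <- assocs |>
    dplyr::inner_join(dplyr::distinct(ortholog_map),
                      by = c(entity_id = "source_id"),
                      relationship = "many-to-many") |>
    dplyr::transmute(entity_id = .data$target_id, relation = .data$relation,
                     class_id = .data$class_id, source = .data$source) |>
    dplyr::distinct(.data$entity_id, .data$relation, .data$class_id,
                    .keep_all = TRUE)
  n_dropped <- sum(!assocs$entity_id %in% ortholog_map$source_id)
  if (n_dropped > 0) {
    message("map_orthologs: dropped ", n_dropped,
            " association(s) with unmapped entities")
  }
  attr(joined, "n_dropped") <- n_dropped
  joined
}

#' Read an association table
#'
#' Reads a tab-separated file with columns `entity_id`, `relation`,
#' `class_id` (header optional; detected from the first line).
#'
#' @param path Path to a TSV file.
#' @return Association tibble.
#' @export
read_associations <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("^entity_id\t", first)
  df <- utils::read.delim(path, header = has_header,
                          stringsAsFactors = FALSE)
  if (!has_header) names(df)[1:3] <- c("entity_id", "relation", "class_id")
  tibble::as_tibble(df)
}
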