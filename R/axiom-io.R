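#' Normalized ontology axiom sets
#'
#' An `axiom_set` is a tibble with one row per retained logical axiom and the
#' columns:
#'
#' * `kind` — `"subclass"` or `"equivalence"`.
#' * `subject` — a bare class name (never a complex expression).
#' * `quantifiers`, `relations` — parallel list-columns holding the
#'   quantifier chain on the right-hand side: `quantifiers[[i]]` is a
#'   character vector over `"existential"`, `"universal"`, `"cardinality"`
#'   and `relations[[i]]` the relation name each quantifier restricts.
#'   Both are `character(0)` when the right-hand side is a plain class.
#' * `filler_kind` — `"named"`, `"union"` or `"intersection"`.
#' * `fillers` — list-column of class names; length 1 for `"named"`,
#'   at least 2 otherwise. Boolean combinations are flat: members are class
#'   names only.
#'
#' Only axioms matching the graph transformation patterns are retained:
#' subclass/equivalence between named classes, and subclass/equivalence of a
#' named class with a quantifier chain over a flat union/intersection (or a
#' single named class). Everything else is counted and reported via
#' `attr(x, "skipped")`, never silently dropped.
#'
#' @param axioms A tibble with the columns above.
#' @param n_records Number of logical-axiom records seen in the source.
#' @param skipped Tibble of skipped records (`line`, `reason`).
#' @return An `axiom_set`: the tibble with attributes `class_names`,
#'   `relation_names`, `n_records` and `skipped`.
#' @keywords internal
new_axiom_set <- function(axioms, n_records = nrow(axioms),
                          skipped = tibble::tibble(line = integer(),
                                                   reason = character())) {
  stopifnot(all(c("kind", "subject", "quantifiers", "relations",
                  "filler_kind", "fillers") %in% names(axioms)))
  axioms <- dplyr::distinct(axioms,
                            .data$kind, .data$subject,
                            purrr::map_chr(.data$quantifiers, paste, collapse = "\r"),
                            purrr::map_chr(.data$relations, paste, collapse = "\r"),
                            .data$filler_kind,
                            purrr::map_chr(.data$fillers, paste, collapse = "\r"),
                            .keep_all = TRUE)[, c("kind", "subject", "quantifiers",
                                                  "relations", "filler_kind", "fillers")]
  structure(
    tibble::as_tibble(axioms),
    class_names = sort_c(unique(c(axioms$subject, unlist(axioms$fillers)))),
    relation_names = sort_c(unique(unlist(axioms$relations))),
    n_records = n_records,
    skipped = skipped,
    class = c("axiom_set", class(tibble::tibble()))
  )
}

#' @export
print.axiom_set <- function(x, ...) {
  cat(sprintf("<axiom_set> %d axioms (%d records, %d skipped), %d classes, %d relations\n",
              nrow(x), attr(x, "n_records"), nrow(attr(x, "skipped")),
              length(attr(x, "class_names")), length(attr(x, "relation_names"))))
  NextMethod()
}

#' Parse ontology axioms into a normalized axiom set
#'
#' Reads logical axioms from one of three dialects and normalizes them to the
#' patterns the graph transformation consumes (see [new_axiom_set()]).
#' Records that do not fit a supported pattern — nested boolean fillers,
#' boolean fillers without a quantifier chain, complex left-hand sides — are
#' skipped with a reason and counted, so that
#' `nrow(result) + nrow(attr(result, "skipped")) == attr(result, "n_records")`.
#'
#' @param path Path to the axiom file.
#' @param dialect One of:
#'   * `"tsv_simple"` — one axiom per line:
#'     `SUBJECT<TAB>SubClassOf|EquivalentTo<TAB>EXPRESSION`, where
#'     `EXPRESSION` is a possibly empty sequence of `some:REL`, `only:REL`,
#'     `card:REL` tokens followed by either a class name or a flat
#'     parenthesized combination `(C1 or C2 ...)` / `(C1 and C2 ...)`.
#'     Blank lines and lines starting with `#` are ignored.
#'   * `"obo"` — OBO 1.4 flat files; `is_a`, `relationship` and
#'     `equivalent_to` tags of `[Term]` stanzas are consumed,
#'     `intersection_of` blocks mixing a genus with relational
#'     differentia are skipped (they are not flat combinations).
#'   * `"owl_functional"` — OWL functional syntax; `SubClassOf` and
#'     `EquivalentClasses` axioms over `ObjectSomeValuesFrom`,
#'     `ObjectAllValuesFrom`, `ObjectMin/Max/ExactCardinality`,
#'     `ObjectUnionOf` and `ObjectIntersectionOf` are consumed.
#' @return An `axiom_set`.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("feeding_behavior\tSubClassOf\tbehavior",
#'              "A\tSubClassOf\tsome:R0 some:R1 (B1 or B2)"), f)
#' ax <- parse_axioms(f, "tsv_simple")
#' ax$subject
#' @export
parse_axioms <- function(path, dialect = c("tsv_simple", "obo", "owl_functional")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("cannot read axiom file: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  res <- switch(dialect,
                tsv_simple = parse_tsv_simple(lines),
                obo = parse_obo(lines),
                owl_functional = parse_owl_functional(lines))
  if (nrow(res$skipped) > 0) {
    message(sprintf("parse_axioms: skipped %d non-conforming record(s)",
                    nrow(res$skipped)))
  }
  new_axiom_set(res$axioms, n_records = res$n_records, skipped = res$skipped)
}

#' Serialize an axiom set to the tsv_simple dialect
#'
#' Inverse of [parse_axioms()] for the `tsv_simple` dialect; parsing the
#' serialized output yields an identical axiom set.
#'
#' @param axioms An `axiom_set`.
#' @param path Optional file to write to; when `NULL` the lines are returned.
#' @return The serialized lines, invisibly when `path` is given.
#' @export
serialize_axioms <- function(axioms, path = NULL) {
  stopifnot(inherits(axioms, "axiom_set"))
  kw <- c(existential = "some", universal = "only", cardinality = "card")
  op <- c(union = "or", intersection = "and")
  lines <- purrr::pmap_chr(
    list(axioms$kind, axioms$subject, axioms$quantifiers,
         axioms$relations, axioms$filler_kind, axioms$fillers),
    function(kind, subject, q, r, fk, f) {
      chain <- if (length(q)) paste0(kw[q], ":", r, collapse = " ") else ""
      filler <- if (fk == "named") f else
        paste0("(", paste(f, collapse = paste0(" ", op[[fk]], " ")), ")")
      expr <- trimws(paste(chain, filler))
      paste(subject, if (kind == "subclass") "SubClassOf" else "EquivalentTo",
            expr, sep = "\t")
    })
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

empty_axiom_tbl <- function() {
  tibble::tibble(kind = character(), subject = character(),
                 quantifiers = list(), relations = list(),
                 filler_kind = character(), fillers = list())
}

axiom_row <- function(kind, subject, quantifiers, relations, filler_kind, fillers) {
  tibble::tibble(kind = kind, subject = subject,
                 quantifiers = list(quantifiers), relations = list(relations),
                 filler_kind = filler_kind, fillers = list(fillers))
}

# Classify a parsed right-hand side against the supported patterns.
# Returns NULL when conforming, otherwise a reason string.
rhs_reason <- function(quantifiers, fillers, filler_kind) {
  if (filler_kind != "named" && length(quantifiers) == 0) {
    return("boolean filler without quantifier chain")
  }
  NULL
}

## ---- tsv_simple ------------------------------------------------------------

parse_expression_tokens <- function(tokens, line_no) {
  quantifiers <- character()
  relations <- character()
  i <- 1L
  while (i <= length(tokens) && grepl("^(some|only|card):", tokens[i])) {
    kw <- sub(":.*$", "", tokens[i])
    rel <- sub("^[a-z]+:", "", tokens[i])
    if (!nzchar(rel)) {
      stop(sprintf("line %d: empty relation name in '%s'", line_no, tokens[i]),
           call. = FALSE)
    }
    quantifiers <- c(quantifiers,
                     c(some = "existential", only = "universal",
                       card = "cardinality")[[kw]])
    relations <- c(relations, rel)
    i <- i + 1L
  }
  rest <- tokens[seq_along(tokens) >= i]
  if (length(rest) == 0) {
    stop(sprintf("line %d: expression has no filler", line_no), call. = FALSE)
  }
  if (length(rest) == 1 && !grepl("[()]", rest)) {
    return(list(quantifiers = quantifiers, relations = relations,
                filler_kind = "named", fillers = rest))
  }
  expr <- paste(rest, collapse = " ")
  if (!grepl("^\\(.*\\)$", expr)) {
    stop(sprintf("line %d: malformed filler expression '%s'", line_no, expr),
         call. = FALSE)
  }
  inner <- trimws(substr(expr, 2, nchar(expr) - 1))
  if (grepl("[()]", inner)) {
    return(list(error = "nested boolean filler"))
  }
  has_or <- grepl("\\bor\\b", inner)
  has_and <- grepl("\\band\\b", inner)
  if (has_or && has_and) {
    return(list(error = "mixed union/intersection filler"))
  }
  if (!has_or && !has_and) {
    stop(sprintf("line %d: parenthesized filler without 'or'/'and': '%s'",
                 line_no, expr), call. = FALSE)
  }
  members <- trimws(strsplit(inner,
                             if (has_or) "\\bor\\b" else "\\band\\b")[[1]])
  members <- members[nzchar(members)]
  if (length(members) < 2) {
    stop(sprintf("line %d: boolean filler needs >= 2 members: '%s'",
                 line_no, expr), call. = FALSE)
  }
  list(quantifiers = quantifiers, relations = relations,
       filler_kind = if (has_or) "union" else "intersection",
       fillers = members)
}

parse_tsv_simple <- function(lines) {
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  idx <- which(keep)
  rows <- list()
  skipped <- list()
  for (j in seq_along(idx)) {
    line_no <- idx[j]
    fields <- strsplit(lines[line_no], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 3) {
      stop(sprintf("line %d: expected 3 tab-separated fields, got %d",
                   line_no, length(fields)), call. = FALSE)
    }
    kind <- switch(fields[2],
                   SubClassOf = "subclass", EquivalentTo = "equivalence",
                   stop(sprintf("line %d: unknown axiom keyword '%s'",
                                line_no, fields[2]), call. = FALSE))
    tokens <- strsplit(trimws(fields[3]), "\\s+")[[1]]
    parsed <- parse_expression_tokens(tokens, line_no)
    if (!is.null(parsed$error)) {
      skipped[[length(skipped) + 1L]] <-
        tibble::tibble(line = line_no, reason = parsed$error)
      next
    }
    reason <- rhs_reason(parsed$quantifiers, parsed$fillers, parsed$filler_kind)
    if (!is.null(reason)) {
      skipped[[length(skipped) + 1L]] <-
        tibble::tibble(line = line_no, reason = reason)
      next
    }
    rows[[length(rows) + 1L]] <-
      axiom_row(kind, fields[1], parsed$quantifiers, parsed$relations,
                parsed$filler_kind, parsed$fillers)
  }
  list(axioms = if (length(rows)) dplyr::bind_rows(rows) else empty_axiom_tbl(),
       skipped = if (length(skipped)) dplyr::bind_rows(skipped) else
         tibble::tibble(line = integer(), reason = character()),
       n_records = length(idx))
}

## ---- OBO 1.4 ---------------------------------------------------------------

parse_obo <- function(lines) {
  lines <- sub("\\s*!.*$", "", lines)        # trailing comments
  rows <- list()
  skipped <- list()
  n_records <- 0L
  cur_id <- NA_character_
  in_term <- FALSE
  intersections <- list()
  int_line <- NA_integer_

  flush_intersection <- function() {
    if (length(intersections) < 2) {
      intersections <<- list()
      return(invisible())
    }
    n_records <<- n_records + 1L
    bare <- vapply(intersections, function(x) is.na(x$rel), logical(1))
    if (all(bare)) {
      rows[[length(rows) + 1L]] <<-
        axiom_row("equivalence", cur_id, character(), character(),
                  "intersection",
                  vapply(intersections, `[[`, "", "cls"))
    } else {
      skipped[[length(skipped) + 1L]] <<-
        tibble::tibble(line = int_line,
                       reason = "genus-differentia intersection (not flat)")
    }
    intersections <<- list()
  }

  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (grepl("^\\[", line)) {
      flush_intersection()
      in_term <- identical(line, "[Term]")
      cur_id <- NA_character_
      next
    }
    if (!in_term || !nzchar(line)) next
    if (grepl("^id:", line)) {
      cur_id <- trimws(sub("^id:", "", line))
    } else if (grepl("^is_obsolete:\\s*true", line)) {
      in_term <- FALSE
      intersections <- list()
    } else if (grepl("^is_a:", line) && !is.na(cur_id)) {
      n_records <- n_records + 1L
      rows[[length(rows) + 1L]] <-
        axiom_row("subclass", cur_id, character(), character(), "named",
                  trimws(sub("^is_a:", "", line)))
    } else if (grepl("^relationship:", line) && !is.na(cur_id)) {
      n_records <- n_records + 1L
      parts <- strsplit(trimws(sub("^relationship:", "", line)), "\\s+")[[1]]
      if (length(parts) == 2) {
        rows[[length(rows) + 1L]] <-
          axiom_row("subclass", cur_id, "existential", parts[1], "named",
                    parts[2])
      } else {
        skipped[[length(skipped) + 1L]] <-
          tibble::tibble(line = i, reason = "malformed relationship tag")
      }
    } else if (grepl("^equivalent_to:", line) && !is.na(cur_id)) {
      n_records <- n_records + 1L
      rows[[length(rows) + 1L]] <-
        axiom_row("equivalence", cur_id, character(), character(), "named",
                  trimws(sub("^equivalent_to:", "", line)))
    } else if (grepl("^intersection_of:", line) && !is.na(cur_id)) {
      parts <- strsplit(trimws(sub("^intersection_of:", "", line)), "\\s+")[[1]]
      if (length(intersections) == 0) int_line <- i
      intersections[[length(intersections) + 1L]] <-
        if (length(parts) == 1) list(rel = NA_character_, cls = parts[1])
        else list(rel = parts[1], cls = parts[2])
    }
  }
  flush_intersection()
  list(axioms = if (length(rows)) dplyr::bind_rows(rows) else empty_axiom_tbl(),
       skipped = if (length(skipped)) dplyr::bind_rows(skipped) else
         tibble::tibble(line = integer(), reason = character()),
       n_records = n_records)
}

## ---- OWL functional syntax -------------------------------------------------

# S-expression style tokenizer: names, '(' and ')'.
owl_tokenize <- function(text) {
  text <- gsub("([()])", " \\1 ", text)
  tokens <- strsplit(trimws(text), "\\s+")[[1]]
  tokens[nzchar(tokens)]
}

# Parse one parenthesized form starting at position i (tokens[i] is the head
# name, tokens[i+1] == "("). Returns list(node, next_i). A node is either a
# character scalar (named class / literal) or list(head = ..., args = list()).
owl_parse_form <- function(tokens, i) {
  head <- tokens[i]
  if (i + 1 > length(tokens) || tokens[i + 1] != "(") {
    return(list(node = head, next_i = i + 1L))
  }
  i <- i + 2L
  args <- list()
  while (i <= length(tokens) && tokens[i] != ")") {
    res <- owl_parse_form(tokens, i)
    args[[length(args) + 1L]] <- res$node
    i <- res$next_i
  }
  if (i > length(tokens)) stop("unbalanced parentheses in OWL functional input",
                               call. = FALSE)
  list(node = list(head = head, args = args), next_i = i + 1L)
}

owl_is_named <- function(node) is.character(node)

# Flatten an OWL class expression into the (chain, filler) shape, or return
# a reason string when it does not conform.
owl_flatten <- function(node) {
  if (owl_is_named(node)) {
    return(list(quantifiers = character(), relations = character(),
                filler_kind = "named", fillers = node))
  }
  head <- node$head
  if (head %in% c("ObjectSomeValuesFrom", "ObjectAllValuesFrom")) {
    if (length(node$args) != 2 || !owl_is_named(node$args[[1]])) {
      return("unsupported restriction shape")
    }
    inner <- owl_flatten(node$args[[2]])
    if (!is.list(inner)) return(inner)
    q <- if (head == "ObjectSomeValuesFrom") "existential" else "universal"
    return(list(quantifiers = c(q, inner$quantifiers),
                relations = c(node$args[[1]], inner$relations),
                filler_kind = inner$filler_kind, fillers = inner$fillers))
  }
  if (head %in% c("ObjectMinCardinality", "ObjectMaxCardinality",
                  "ObjectExactCardinality")) {
    # (n R [C]); the cardinality value is not retained.
    if (length(node$args) < 2 || !owl_is_named(node$args[[2]])) {
      return("unsupported cardinality shape")
    }
    inner <- if (length(node$args) >= 3) owl_flatten(node$args[[3]]) else
      list(quantifiers = character(), relations = character(),
           filler_kind = "named", fillers = "owl:Thing")
    if (!is.list(inner)) return(inner)
    return(list(quantifiers = c("cardinality", inner$quantifiers),
                relations = c(node$args[[2]], inner$relations),
                filler_kind = inner$filler_kind, fillers = inner$fillers))
  }
  if (head %in% c("ObjectUnionOf", "ObjectIntersectionOf")) {
    if (!all(vapply(node$args, owl_is_named, logical(1)))) {
      return("nested boolean filler")
    }
    if (length(node$args) < 2) return("boolean combination with < 2 members")
    return(list(quantifiers = character(), relations = character(),
                filler_kind = if (head == "ObjectUnionOf") "union" else
                  "intersection",
                fillers = unlist(node$args)))
  }
  paste0("unsupported class expression: ", head)
}

parse_owl_functional <- function(lines) {
  text <- paste(lines, collapse = "\n")
  text <- gsub("(?m)^\\s*(Prefix|Import)\\([^\n]*$", "", text, perl = TRUE)
  tokens <- owl_tokenize(text)
  # unwrap Ontology( ... )
  forms <- list()
  i <- 1L
  while (i <= length(tokens)) {
    if (tokens[i] == "Ontology" && i < length(tokens) && tokens[i + 1] == "(") {
      i <- i + 2L
      # ontology IRI tokens until first axiom form
      while (i <= length(tokens) && tokens[i] != ")" &&
             !(i < length(tokens) && tokens[i + 1] == "(")) i <- i + 1L
      next
    }
    if (tokens[i] == ")") { i <- i + 1L; next }
    res <- owl_parse_form(tokens, i)
    forms[[length(forms) + 1L]] <- res$node
    i <- res$next_i
  }

  logical_heads <- c("SubClassOf", "EquivalentClasses", "DisjointClasses",
                     "DisjointUnion", "SubObjectPropertyOf",
                     "ObjectPropertyDomain", "ObjectPropertyRange",
                     "TransitiveObjectProperty", "FunctionalObjectProperty",
                     "InverseObjectProperties", "ClassAssertion",
                     "ObjectPropertyAssertion")
  rows <- list()
  skipped <- list()
  n_records <- 0L
  add_skip <- function(reason) {
    skipped[[length(skipped) + 1L]] <<- tibble::tibble(line = NA_integer_,
                                                       reason = reason)
  }
  handle_pair <- function(kind, subj, rhs_node) {
    if (!owl_is_named(subj)) {
      add_skip("complex left-hand side")
      return(invisible())
    }
    flat <- owl_flatten(rhs_node)
    if (!is.list(flat)) {
      add_skip(flat)
      return(invisible())
    }
    reason <- rhs_reason(flat$quantifiers, flat$fillers, flat$filler_kind)
    if (!is.null(reason)) {
      add_skip(reason)
      return(invisible())
    }
    rows[[length(rows) + 1L]] <<-
      axiom_row(kind, subj, flat$quantifiers, flat$relations,
                flat$filler_kind, flat$fillers)
  }
  for (form in forms) {
    if (owl_is_named(form) || !(form$head %in% logical_heads)) next
    if (form$head == "SubClassOf" && length(form$args) == 2) {
      n_records <- n_records + 1L
      handle_pair("subclass", form$args[[1]], form$args[[2]])
    } else if (form$head == "EquivalentClasses" && length(form$args) >= 2) {
      for (k in 2:length(form$args)) {
        n_records <- n_records + 1L
        handle_pair("equivalence", form$args[[1]], form$args[[k]])
      }
    } else {
      n_records <- n_records + 1L
      add_skip(paste0("unsupported logical axiom: ", form$head))
    }
  }
  list(axioms = if (length(rows)) dplyr::bind_rows(rows) else empty_axiom_tbl(),
       skipped = if (length(skipped)) dplyr::bind_rows(skipped) else
         tibble::tibble(line = integer(), reason = character()),
       n_records = n_records)
}
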