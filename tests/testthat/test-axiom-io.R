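write_axiom_file <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("tsv_simple parses plain subclass and equivalence axioms", {
  f <- write_axiom_file(c("feeding_behavior\tSubClassOf\tbehavior",
                          "A\tEquivalentTo\tB"))
  ax <- parse_axioms(f, "tsv_simple")
  expect_s3_class(ax, "axiom_set")
  expect_equal(nrow(ax), 2)
  expect_equal(ax$kind, c("subclass", "equivalence"))
  expect_equal(ax$subject, c("feeding_behavior", "A"))
  expect_equal(ax$filler_kind, c("named", "named"))
  expect_equal(unlist(ax$fillers), c("behavior", "B"))
  expect_equal(lengths(ax$relations), c(0L, 0L))
})

test_that("tsv_simple parses quantifier chains over boolean fillers", {
  f <- write_axiom_file("A\tSubClassOf\tsome:R0 some:R1 (B1 or B2)")
  ax <- parse_axioms(f, "tsv_simple")
  expect_equal(nrow(ax), 1)
  expect_equal(ax$quantifiers[[1]], c("existential", "existential"))
  expect_equal(ax$relations[[1]], c("R0", "R1"))
  expect_equal(ax$filler_kind, "union")
  expect_equal(ax$fillers[[1]], c("B1", "B2"))

  f2 <- write_axiom_file(c("A\tSubClassOf\tonly:R C",
                           "A\tEquivalentTo\tcard:R (C1 and C2 and C3)"))
  ax2 <- parse_axioms(f2, "tsv_simple")
  expect_equal(ax2$quantifiers[[1]], "universal")
  expect_equal(ax2$quantifiers[[2]], "cardinality")
  expect_equal(ax2$filler_kind, c("named", "intersection"))
  expect_equal(ax2$fillers[[2]], c("C1", "C2", "C3"))
})

test_that("class and relation inventories cover all mentioned identifiers", {
  f <- write_axiom_file(c("A\tSubClassOf\tsome:R0 (B1 or B2)",
                          "C\tSubClassOf\tD"))
  ax <- parse_axioms(f, "tsv_simple")
  expect_setequal(attr(ax, "class_names"), c("A", "B1", "B2", "C", "D"))
  expect_setequal(attr(ax, "relation_names"), "R0")
})

test_that("non-conforming records are skipped with a count, never dropped silently", {
  f <- write_axiom_file(c("A\tSubClassOf\tB",
                          "A\tSubClassOf\tsome:R ((B1 or B2) or B3)",
                          "A\tSubClassOf\t(B1 or B2)",
                          "C\tSubClassOf\tD"))
  expect_message(ax <- parse_axioms(f, "tsv_simple"), "skipped 2")
  expect_equal(nrow(ax), 2)
  expect_equal(attr(ax, "n_records"), 4)
  expect_equal(nrow(attr(ax, "skipped")), 2)
  expect_equal(nrow(ax) + nrow(attr(ax, "skipped")), attr(ax, "n_records"))
})

test_that("malformed records raise errors naming the line", {
  f <- write_axiom_file(c("A\tSubClassOf\tB", "A only-two-fields"))
  expect_error(parse_axioms(f, "tsv_simple"), "line 2")
  f2 <- write_axiom_file("A\tIsKindOf\tB")
  expect_error(parse_axioms(f2, "tsv_simple"), "line 1")
  expect_error(parse_axioms(tempfile(), "tsv_simple"), "cannot read")
})

test_that("serialization round-trips through the parser", {
  f <- write_axiom_file(c("feeding_behavior\tSubClassOf\tbehavior",
                          "A\tEquivalentTo\tB",
                          "A\tSubClassOf\tsome:R0 some:R1 (B1 or B2)",
                          "P\tEquivalentTo\tsome:has-part (F1 and F2)",
                          "Q\tSubClassOf\tonly:r card:s X"))
  ax <- parse_axioms(f, "tsv_simple")
  once <- serialize_axioms(ax)
  f2 <- write_axiom_file(once)
  twice <- serialize_axioms(parse_axioms(f2, "tsv_simple"))
  expect_identical(once, twice)
})

test_that("OBO stanzas map onto the axiom patterns", {
  f <- write_axiom_file(c(
    "format-version: 1.4", "",
    "[Term]", "id: MP:0001", "name: thing",
    "is_a: MP:0000 ! parent",
    "relationship: part_of UBERON:1", "",
    "[Term]", "id: MP:0002",
    "equivalent_to: HP:0002",
    "intersection_of: GO:1",
    "intersection_of: GO:2", "",
    "[Term]", "id: MP:0003",
    "intersection_of: MP:0000",
    "intersection_of: has_part GO:3", "",
    "[Term]", "id: MP:9999", "is_obsolete: true",
    "is_a: MP:0000"))
  ax <- suppressMessages(parse_axioms(f, "obo"))
  expect_equal(attr(ax, "n_records"), 5)  # is_a, relationship, equiv, 2 blocks
  expect_equal(nrow(ax), 4)
  rel <- ax[lengths(ax$relations) == 1, ]
  expect_equal(rel$relations[[1]], "part_of")
  expect_equal(rel$quantifiers[[1]], "existential")
  inter <- ax[ax$filler_kind == "intersection", ]
  expect_equal(inter$subject, "MP:0002")
  expect_equal(inter$fillers[[1]], c("GO:1", "GO:2"))
  expect_equal(attr(ax, "skipped")$reason,
               "genus-differentia intersection (not flat)")
})

test_that("OWL functional syntax maps onto the axiom patterns", {
  f <- write_axiom_file(c(
    "Prefix(:=<http://example.org/>)",
    "Ontology(<http://example.org/onto>",
    "Declaration(Class(:A))",
    "SubClassOf(:A :B)",
    "EquivalentClasses(:A :C)",
    "SubClassOf(:A ObjectSomeValuesFrom(:R ObjectUnionOf(:B1 :B2)))",
    "SubClassOf(:A ObjectSomeValuesFrom(:R0 ObjectAllValuesFrom(:R1 :C)))",
    "SubClassOf(:A ObjectMinCardinality(2 :R :C))",
    "SubClassOf(:A ObjectUnionOf(:B1 :B2))",
    "DisjointClasses(:A :B)",
    ")"))
  ax <- suppressMessages(parse_axioms(f, "owl_functional"))
  expect_equal(attr(ax, "n_records"), 7)
  expect_equal(nrow(ax), 5)
  expect_equal(nrow(attr(ax, "skipped")), 2)
  chain <- ax[lengths(ax$relations) == 2, ]
  expect_equal(chain$quantifiers[[1]], c("existential", "universal"))
  expect_equal(chain$relations[[1]], c(":R0", ":R1"))
  card <- ax[vapply(ax$quantifiers, function(q) "cardinality" %in% q,
                    logical(1)), ]
  expect_equal(card$relations[[1]], ":R")  # the cardinality value is dropped
  expect_equal(card$fillers[[1]], ":C")
})

test_that("parsing is deterministic for a fixed file", {
  f <- write_axiom_file(c("A\tSubClassOf\tsome:R (B1 or B2)",
                          "C\tSubClassOf\tD"))
  expect_identical(serialize_axioms(parse_axioms(f, "tsv_simple")),
                   serialize_axioms(parse_axioms(f, "tsv_simple")))
})
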