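test_that("BoolNet text parses into rules, inputs, and truth tables", {
  net <- parse_boolnet("targets, factors\nA, B\nB, A")
  expect_s3_class(net, "boolean_network")
  expect_identical(net$nodes, c("A", "B"))
  expect_identical(net$rules$A$inputs, "B")
  expect_identical(net$rules$A$table, c(0L, 1L))
  expect_identical(net$rules$B$table, c(0L, 1L))

  neg <- parse_boolnet("targets, factors\nA, !A")
  expect_identical(neg$rules$A$inputs, "A")
  expect_identical(neg$rules$A$table, c(1L, 0L))

  # comments, blank lines, repeated variables deduplicated in input order
  net2 <- parse_boolnet("# a comment\n\ntargets, factors\nA, B & B\nB, A | 0")
  expect_identical(net2$rules$A$inputs, "B")
  expect_identical(net2$rules$A$table, c(0L, 1L))
})

test_that("malformed BoolNet documents raise targeted errors", {
  expect_error(parse_boolnet("A, B\nB, A"), class = "bn_format_error")
  expect_error(parse_boolnet("targets, factors\nA, B\nA, 1\nB, A"),
               regexp = "duplicate", class = "bn_format_error")
  expect_error(parse_boolnet("targets, factors\nA, C"),
               regexp = "undefined node 'C'", class = "bn_symbol_error")
  expect_error(parse_boolnet("targets, factors\nA, B &\nB, A"),
               regexp = "line 2", class = "bn_parse_error")
  expect_error(parse_boolnet("targets, factors, probabilities\nA, B, 0.5"),
               regexp = "probabilistic", class = "bn_format_error")
  expect_error(parse_boolnet("targets, factors\nA, B, 0.7\nB, A, 0.3"),
               class = "bn_format_error")
  expect_error(parse_boolnet("targets, factors\nA, timeis(3)"),
               regexp = "unsupported construct", class = "bn_parse_error")
})

test_that("truth-table compilation uses the first input as least-significant bit", {
  and_expr <- parse_boolnet("targets, factors\nx1, x1\nx2, x2\ny, x1 & x2")$rules$y$expr
  expect_identical(compile_truth_table(and_expr, c("x1", "x2")),
                   c(0L, 0L, 0L, 1L))
  xor <- parse_boolnet(
    "targets, factors\nx1, x1\nx2, x2\ny, (x1 & !x2) | (!x1 & x2)")
  expect_identical(xor$rules$y$table, c(0L, 1L, 1L, 0L))
  const <- parse_boolnet("targets, factors\nA, 1")
  expect_identical(const$rules$A$inputs, character(0))
  expect_identical(const$rules$A$table, 1L)
  expect_error(compile_truth_table(and_expr, "x1"),
               class = "bn_symbol_error")

  # bit-order convention is observable: direct evaluation matches lookup
  net <- random_boolean_network(5, 3, seed = 11)
  for (h in net$nodes) {
    rule <- net$rules[[h]]
    expect_identical(compile_truth_table(rule$expr, rule$inputs), rule$table)
  }
})

test_that("SBML-qual import compiles transitions to Boolean rules", {
  doc <- make_sbml_qual(
    list(qs("X"), qs("Y")),
    list(list(inputs = "X", output = "Y", default_level = 0L,
              terms = list(list(
                level = 1L,
                math = "<apply><not/><apply><eq/><ci>X</ci><cn>1</cn></apply></apply>"))))
  )
  net <- parse_sbml_qual(doc)
  expect_identical(net$nodes, c("X", "Y"))
  expect_identical(net$rules$Y$inputs, "X")
  expect_identical(net$rules$Y$table, c(1L, 0L))  # Y := NOT X
  # X has no transition: constant at default initial level 0
  expect_identical(net$rules$X$table, 0L)
})

test_that("SBML-qual rejects non-Boolean constructs", {
  expect_error(parse_sbml_qual(make_sbml_qual(list(qs("X", maxLevel = 2L)))),
               regexp = "maxLevel", class = "bn_unsupported_error")
  arith <- make_sbml_qual(
    list(qs("X"), qs("Y")),
    list(list(inputs = "X", output = "Y", default_level = 0L,
              terms = list(list(
                level = 1L,
                math = "<apply><plus/><ci>X</ci><cn>1</cn></apply>")))))
  expect_error(parse_sbml_qual(arith), class = "bn_unsupported_error")
  expect_error(parse_sbml_qual("<sbml><unclosed"), class = "bn_parse_error")
})

test_that("transition-free SBML species form an all-constant network", {
  doc <- make_sbml_qual(list(qs("A", initialLevel = 1L), qs("B")))
  net <- parse_sbml_qual(doc)
  expect_identical(net$rules$A$table, 1L)
  expect_identical(net$rules$B$table, 0L)
  aset <- find_attractors(net)
  expect_length(aset$attractors, 1L)
  expect_identical(unname(aset$attractors[[1]]$states[1, ]), c(1L, 0L))
  expect_identical(aset$attractors[[1]]$basin_size, 4L)
})

test_that("defaultTerm supplies uncovered assignments", {
  # Y := X1 AND X2 expressed with one functionTerm and default 0
  doc <- make_sbml_qual(
    list(qs("X1"), qs("X2"), qs("Y")),
    list(list(inputs = c("X1", "X2"), output = "Y", default_level = 0L,
              terms = list(list(
                level = 1L,
                math = paste0("<apply><and/>",
                              "<apply><eq/><ci>X1</ci><cn>1</cn></apply>",
                              "<apply><eq/><ci>X2</ci><cn>1</cn></apply>",
                              "</apply>"))))))
  net <- parse_sbml_qual(doc)
  expect_identical(net$rules$Y$table, c(0L, 0L, 0L, 1L))
})

test_that("write/parse round-trips preserve names, inputs, and tables", {
  check_roundtrip <- function(net) {
    back <- parse_boolnet(paste(write_boolnet(net), collapse = "\n"))
    expect_identical(back$nodes, net$nodes)
    for (h in net$nodes) {
      expect_identical(back$rules[[h]]$inputs, net$rules[[h]]$inputs)
      expect_identical(back$rules[[h]]$table, net$rules[[h]]$table)
    }
  }
  for (name in c("toggle", "negator", "chain3", "diamond", "star8",
                 "bottleneck12")) {
    check_roundtrip(fixture(name))
  }
  for (seed in 1:50) {
    check_roundtrip(random_boolean_network(6, 1L + seed %% 3L, seed = seed))
  }
})

test_that("a model hand-encoded in both formats is equivalent", {
  # A = B OR C, B = NOT A, C = A AND B
  bn <- parse_boolnet(
    "targets, factors\nA, B | C\nB, !A\nC, A & B")
  doc <- make_sbml_qual(
    list(qs("A"), qs("B"), qs("C")),
    list(
      list(inputs = c("B", "C"), output = "A", default_level = 0L,
           terms = list(list(
             level = 1L,
             math = paste0("<apply><or/>",
                           "<apply><eq/><ci>B</ci><cn>1</cn></apply>",
                           "<apply><eq/><ci>C</ci><cn>1</cn></apply>",
                           "</apply>")))),
      list(inputs = "A", output = "B", default_level = 1L,
           terms = list(list(
             level = 0L,
             math = "<apply><eq/><ci>A</ci><cn>1</cn></apply>"))),
      list(inputs = c("A", "B"), output = "C", default_level = 0L,
           terms = list(list(
             level = 1L,
             math = paste0("<apply><and/>",
                           "<apply><eq/><ci>A</ci><cn>1</cn></apply>",
                           "<apply><eq/><ci>B</ci><cn>1</cn></apply>",
                           "</apply>"))))))
  sb <- parse_sbml_qual(doc)
  expect_identical(sb$nodes, bn$nodes)
  for (h in bn$nodes) {
    expect_identical(sb$rules[[h]]$inputs, bn$rules[[h]]$inputs)
    expect_identical(sb$rules[[h]]$table, bn$rules[[h]]$table)
  }
  g_bn <- build_interaction_graph(bn)
  g_sb <- build_interaction_graph(sb)
  expect_identical(igraph::as_edgelist(g_sb), igraph::as_edgelist(g_bn))
})
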