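test_that("TSV parsing: toy network, de-duplication, degenerate input", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "A\tC", "A\tE", "", "B\tC", "B\tD", "C\tB"), tf)
  net <- read_network(tf, "tsv")
  expect_equal(n_nodes(net), 5)
  expect_equal(n_arcs(net), 5)
  expect_equal(net$nodes, c("A", "C", "E", "B", "D"))  # first appearance

  writeLines(c("A\tB", "A\tB"), tf)
  expect_equal(n_arcs(read_network(tf, "tsv")), 1)

  writeLines(character(0), tf)
  empty <- read_network(tf, "tsv")
  expect_equal(n_nodes(empty), 0)
  expect_equal(n_arcs(empty), 0)

  writeLines(c("Regulator\tTarget", "A\tB"), tf)
  expect_equal(n_arcs(read_network(tf, "tsv")), 1)

  writeLines(c("A\tB", "oops"), tf)
  expect_error(read_network(tf, "tsv"), "line 2")
})

test_that("SIF parsing stores the relation as arc sign", {
  tf <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("A\tactivates\tB", "B\tinhibits\tC"), tf)
  net <- read_network(tf)
  expect_equal(net$arcs$sign, c("activates", "inhibits"))
  expect_error({
    writeLines("A\tB", tf)
    read_network(tf, "sif")
  }, "line 1")
})

test_that("round-trip preserves node and arc sets in every dialect", {
  net <- toy_fig_a()
  for (fmt in c("tsv", "sif", "graphml")) {
    tf <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_network(net, tf, fmt)
    back <- read_network(tf, fmt)
    expect_setequal(back$nodes, net$nodes)
    expect_setequal(paste(back$arcs$from, back$arcs$to),
                    paste(net$arcs$from, net$arcs$to))
  }
})

test_that("underlying undirected graph merges antiparallel arcs, drops loops", {
  expect_equal(nrow(underlying_undirected(
    regulatory_network(c("a", "b"), c("b", "a")))$edges), 1)
  expect_equal(nrow(underlying_undirected(
    regulatory_network("a", "a"))$edges), 0)
  expect_equal(nrow(underlying_undirected(
    regulatory_network(c("a", "b"), c("b", "c")))$edges), 2)
  # idempotent in edge count on an already symmetric network
  sym <- regulatory_network(c("a", "b", "b", "c"), c("b", "a", "c", "b"))
  expect_equal(nrow(underlying_undirected(sym)$edges), 2)
})

test_that("neighbourhoods exclude self-loops and reject unknown nodes", {
  net <- regulatory_network(c("a", "b"), c("b", "b"))
  expect_equal(in_neighbors(net, "b"), "a")
  expect_equal(in_neighbors(net, "a"), character(0))
  expect_equal(out_neighbors(net, "b"), character(0))  # self-loop excluded
  expect_error(in_neighbors(net, "zz"), "unknown node")
  expect_equal(unname(out_degrees(net)[["b"]]), 0)
})
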