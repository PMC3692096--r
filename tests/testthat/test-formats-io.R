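test_that("matrix parsing honors the header/row contract and missing tokens", {
  f <- withr::local_tempfile(lines = c("gene\ts1\ts2",
                                       "TP53\t0.5\t-1.2",
                                       "BRAF\tNA\t3"))
  m <- read_matrix(f, "expr", "continuous")
  expect_equal(matrix_genes(m), c("TP53", "BRAF"))
  expect_equal(matrix_samples(m), c("s1", "s2"))
  expect_equal(unname(m$values["TP53", ]), c(0.5, -1.2))
  expect_true(is.na(m$values["BRAF", "s1"]))
  expect_equal(m$values["BRAF", "s2"], 3)

  for (tok in c("NA", "nan", "NaN", "")) {
    f2 <- withr::local_tempfile(lines = c("gene\ts1\ts2",
                                          sprintf("X\t%s\t1", tok)))
    expect_true(is.na(read_matrix(f2, "p", "continuous")$values["X", "s1"]),
                info = tok)
  }
})

test_that("matrix parser rejects ragged rows, duplicates and empty layouts", {
  ragged <- withr::local_tempfile(lines = c("gene\ts1\ts2", "A\t1\t2", "B\t1"))
  expect_error(read_matrix(ragged, "p", "continuous"), "line 3")
  dup <- withr::local_tempfile(lines = c("gene\ts1", "A\t1", "A\t2"))
  expect_error(read_matrix(dup, "p", "continuous"), "duplicate gene")
  nosamp <- withr::local_tempfile(lines = c("gene", "A"))
  expect_error(read_matrix(nosamp, "p", "continuous"), "zero sample")
  junk <- withr::local_tempfile(lines = c("gene\ts1", "A\tfoo"))
  expect_error(read_matrix(junk, "p", "continuous"), "line 2")
})

test_that("matrix write-then-read round-trips exactly, missing preserved", {
  set.seed(11)
  m <- random_matrix(5, 10, platform = "rt", missing_frac = 0.2)
  f <- withr::local_tempfile()
  write_matrix(m, f)
  m2 <- read_matrix(f, "rt", "continuous")
  expect_identical(m2$values, m$values)
  expect_identical(matrix_genes(m2), matrix_genes(m))
})

test_that("binary matrices enforce the 0/1 domain", {
  v <- matrix(c(0, 1, NA, 1), 2, 2, dimnames = list(c("A", "B"), c("s1", "s2")))
  expect_s3_class(omics_matrix(v, "mut", "binary"), "omics_matrix")
  v[1, 1] <- 2
  expect_error(omics_matrix(v, "mut", "binary"), "outside")
})

test_that("annotation tables parse, handle headers/blank categories, round-trip", {
  f <- withr::local_tempfile(lines = c("s1\thyper", "s2\tnonhyper"))
  a <- read_annotation(f, "grp")
  expect_equal(unname(annotation_of(a, c("s1", "s2"))), c("hyper", "nonhyper"))
  expect_true(is.na(annotation_of(a, "never_seen")))

  f2 <- withr::local_tempfile(lines = c("sample\tcategory", "s1\t", "s2\tX"))
  a2 <- read_annotation(f2, "grp")
  expect_true(is.na(annotation_of(a2, "s1")))

  conflict <- withr::local_tempfile(lines = c("s1\tX", "s1\tY"))
  expect_error(read_annotation(conflict), "re-assigned")

  set.seed(5)
  big <- sample_annotation(
    stats::setNames(sample(c("a", "b", "c", NA), 100, replace = TRUE),
                    sprintf("s%03d", 1:100)), "big")
  f3 <- withr::local_tempfile()
  write_annotation(big, f3)
  expect_identical(read_annotation(f3, "big")$assignments, big$assignments)
})

test_that("gene sets dedupe keeping first occurrence and round-trip", {
  f <- withr::local_tempfile(lines = c("# comment", "BRAF", "BRAF", "MYC"))
  gs <- read_gene_set(f, "x")
  expect_equal(gs$members, c("BRAF", "MYC"))
  empty <- withr::local_tempfile(lines = "# only a comment")
  expect_error(read_gene_set(empty), "no symbols")

  set.seed(6)
  syms <- unique(replicate(50, paste(sample(LETTERS, 5), collapse = "")))
  f2 <- withr::local_tempfile()
  write_gene_set(gene_set(syms, "r"), f2)
  expect_equal(read_gene_set(f2)$members, syms)
})

test_that("SIF parsing maps relations, defaults to protein, rejects bad lines", {
  f <- withr::local_tempfile(lines = c("A\tpp\tB", "A\t-a>\tC", "C\t-t|\tA",
                                       "A\tpp\tA"))
  g <- read_network_sif(f, "trk")
  expect_setequal(graph_nodes(g)$name, c("A", "B", "C"))
  expect_true(all(graph_nodes(g)$type == "protein"))
  e <- graph_edges(g)
  expect_equal(nrow(e), 4L)
  expect_setequal(e$type, c("undirected", "activates", "inhibits"))
  expect_true(all(e$track == "trk"))
  expect_true(any(e$from == "A" & e$to == "A"))  # loop accepted

  bad <- withr::local_tempfile(lines = c("A\tpp\tB", "A\tpp"))
  expect_error(read_network_sif(bad, "t"), "line 2")
  unk <- withr::local_tempfile(lines = "A\tbinds\tB")
  expect_error(read_network_sif(unk, "t"), "unknown relation")
})

test_that("a random SIF round-trips with equal node and edge counts", {
  set.seed(7)
  g <- random_graph(30, 200, track = "rand")
  f <- withr::local_tempfile()
  write_network_sif(g, f)
  g2 <- read_network_sif(f, "rand")
  expect_equal(nrow(graph_edges(g2)), 200L)
  expect_setequal(graph_nodes(g2)$name, graph_nodes(g)$name)
  expect_true(edges_equal(graph_edges(g2), graph_edges(g)))
})

test_that("typed dialect parses nodes and edges with vocabulary checks", {
  f <- withr::local_tempfile(lines = c("protein\tA", "protein\tB", "complex\tC",
                                       "A\tB\t-t|", "A\tC\tcomponent>"))
  g <- read_network_typed(f, "trk")
  expect_equal(graph_nodes(g)$type[graph_nodes(g)$name == "C"], "complex")
  e <- graph_edges(g)
  expect_equal(e$type[e$from == "A" & e$to == "B"], "inhibits")
  expect_equal(e$type[e$from == "A" & e$to == "C"], "component")

  expect_error(read_network_typed(
    withr::local_tempfile(lines = c("protein\tA", "A\tB\t-a>")), "t"),
    "undeclared node")
  expect_error(read_network_typed(
    withr::local_tempfile(lines = "gene\tA"), "t"), "unknown entity type")
  expect_error(read_network_typed(
    withr::local_tempfile(lines = c("protein\tA", "protein\tB", "A\tB\tzaps")), "t"),
    "unknown relation")
})

test_that("the generated cohort pathway round-trips through the typed dialect", {
  co <- generate_cohort(cohort_spec(n_samples = 30, seed = 3))
  f <- withr::local_tempfile()
  write_network_typed(co$graph, f)
  g2 <- read_network_typed(f, "crc_pathway")
  expect_identical(graph_nodes(g2), graph_nodes(co$graph))
  expect_true(edges_equal(graph_edges(g2), graph_edges(co$graph)))
})
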