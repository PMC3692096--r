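scene_fixture <- function(n_genes = 2, n_samples = 10, n_rings = 2, seed = 5,
                          mode = "full") {
  set.seed(seed)
  mats <- lapply(seq_len(n_rings), function(i)
    random_matrix(n_genes, n_samples, platform = paste0("p", i), missing_frac = 0.1))
  genes <- matrix_genes(mats[[1]])
  edges <- if (n_genes >= 2) {
    data.frame(from = genes[-length(genes)], to = genes[-1],
               type = "activates", track = "base")
  } else {
    data.frame(from = character(), to = character(), type = character(),
               track = character())
  }
  graph <- pathway_graph(data.frame(name = genes, type = "protein"), edges)
  uni <- sample_universe(mats)
  rings <- lapply(mats, ring_spec)
  glyphs <- if (mode == "full") {
    stats::setNames(lapply(genes, build_glyph, rings = rings, order = uni), genes)
  } else {
    ann <- sample_annotation(
      stats::setNames(rep(c("x", "y"), length.out = n_samples), uni), "grp")
    p <- partition_samples(uni, ann)
    stats::setNames(lapply(genes, build_glyph, rings = rings, partition = p), genes)
  }
  layout <- layout_graph(graph, seed = seed)
  assemble_scene(graph, glyphs, layout, c(base = "#7A28A8"))
}

test_that("layout is deterministic, centered for one node, non-overlapping", {
  g1 <- pathway_graph(data.frame(name = "A", type = "protein"))
  l1 <- layout_graph(g1, seed = 1)
  expect_equal(nrow(l1$coords), 1L)
  expect_true(all(is.finite(l1$coords)))

  set.seed(4)
  g <- random_graph(15, 25)
  la <- layout_graph(g, seed = 9)
  lb <- layout_graph(g, seed = 9)
  expect_identical(la$coords, lb$coords)
  cfg <- scene_config()
  d <- as.matrix(dist(la$coords))
  diag(d) <- Inf
  expect_true(min(d) >= cfg$node_sep - 1e-6)  # >= glyph diameter separation
  expect_error(layout_graph(pathway_graph()), "empty graph")
})

test_that("edge fragments carry the right terminator and track color", {
  g <- pathway_graph(data.frame(name = c("A", "B"), type = "protein"),
                     data.frame(from = "A", to = "B", type = "inhibits",
                                track = "reg"))
  lay <- layout_graph(g, seed = 1)
  frag <- paste(render_edge(graph_edges(g)[1, ], lay, c(reg = "#112233")),
                collapse = "\n")
  expect_match(frag, 'class="tbar"')
  expect_no_match(frag, "arrowhead")
  expect_match(frag, "#112233")

  act <- render_edge(list(from = "A", to = "B", type = "activates", track = "reg"),
                     lay, c(reg = "#112233"))
  expect_match(paste(act, collapse = ""), 'class="arrowhead"')
  dashed <- render_edge(list(from = "A", to = "B", type = "component", track = "reg"),
                        lay, c(reg = "#112233"))
  expect_match(paste(dashed, collapse = ""), "stroke-dasharray")
  expect_error(render_edge(list(from = "A", to = "B", type = "zaps", track = "reg"),
                           lay, c(reg = "#112233")),
               "unknown edge type")
})

test_that("parallel edges from different tracks get distinct colored paths", {
  g <- pathway_graph(data.frame(name = c("A", "B"), type = "protein"),
                     data.frame(from = c("A", "A"), to = c("B", "B"),
                                type = c("activates", "undirected"),
                                track = c("reg", "ppi")))
  lay <- layout_graph(g, seed = 2)
  scene <- assemble_scene(g, layout = lay,
                          track_colors = c(reg = "#7A28A8", ppi = "#8B5A2B"))
  svg <- write_svg(scene)
  expect_equal(count_class(svg, "edge"), 2L)
  expect_match(svg, "#7A28A8")
  expect_match(svg, "#8B5A2B")
  lines <- grep('class="edge-line"', strsplit(svg, "\n")[[1]], value = TRUE)
  expect_length(unique(lines), 2L)  # offset paths, none coincide
})

test_that("node fragments: sector counts in full mode, shapes for typed nodes", {
  sc <- scene_fixture(n_genes = 1, n_samples = 10, n_rings = 2)
  frag <- paste(render_node("G01", "protein", sc$glyphs[["G01"]], sc$layout),
                collapse = "\n")
  expect_equal(lengths(regmatches(frag, gregexpr('class="spoke"', frag))), 20L)
  expect_match(frag, 'class="label"')

  g <- pathway_graph(data.frame(name = "CPX", type = "complex"))
  lay <- layout_graph(g, seed = 1)
  cf <- paste(render_node("CPX", "complex", NULL, lay), collapse = "\n")
  expect_match(cf, 'class="shape"')
  expect_no_match(cf, 'class="spoke"')
})

test_that("aggregated segments honor size-proportional extents", {
  set.seed(8)
  m <- random_matrix(1, 4, platform = "p1", missing_frac = 0)
  uni <- matrix_samples(m)
  ann <- sample_annotation(stats::setNames(c("a", "a", "a", "b"), uni), "grp")
  p <- partition_samples(uni, ann)
  gl <- build_glyph("G01", list(ring_spec(m)), partition = p)
  expect_equal(gl$geometry$extent, c(270, 90))
  g <- pathway_graph(data.frame(name = "G01", type = "protein"))
  frag <- paste(render_node("G01", "protein", gl, layout_graph(g, 1)),
                collapse = "\n")
  expect_equal(lengths(regmatches(frag, gregexpr('class="segment"', frag))), 2L)
})

test_that("write_svg emits well-formed XML with exact class combinatorics", {
  sc <- scene_fixture(n_genes = 2, n_samples = 10, n_rings = 2)
  svg <- write_svg(sc)
  doc <- xml2::read_xml(svg)
  expect_equal(xml2::xml_name(doc), "svg")
  expect_equal(count_class(svg, "spoke"), 2 * 2 * 10)
  expect_equal(count_class(svg, "node"), 2L)
  expect_equal(count_class(svg, "edge"), 1L)
  expect_equal(count_class(svg, "legend"), 1L)
  # legend lists rings in position order
  expect_true(regexpr("ring 1 [^<]*p1", svg) < regexpr("ring 2 [^<]*p2", svg))
})

test_that("an empty scene still serializes to a well-formed svg document", {
  scene <- assemble_scene(pathway_graph())
  svg <- write_svg(scene)
  doc <- xml2::read_xml(svg)
  expect_equal(xml2::xml_name(doc), "svg")
  expect_equal(count_class(svg, "spoke"), 0L)
  expect_equal(count_class(svg, "node"), 0L)
})

test_that("serialization is byte-identical for identical scenes and guards state", {
  sc1 <- scene_fixture(seed = 17)
  sc2 <- scene_fixture(seed = 17)
  expect_identical(write_svg(sc1), write_svg(sc2))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_svg(sc1, f1); write_svg(sc2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_error(write_svg(list(graph = 1)), "not laid out")
  expect_error(assemble_scene(pathway_graph(data.frame(name = "A", type = "protein")),
                              glyphs = list(), layout = NULL),
               "needs a layout")
})

test_that("scene assembly rejects glyphs for absent genes", {
  sc <- scene_fixture()
  stray <- sc$glyphs
  names(stray)[1] <- "NOT_IN_GRAPH"
  expect_error(assemble_scene(sc$graph, stray, sc$layout, sc$track_colors),
               "absent from graph")
})
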