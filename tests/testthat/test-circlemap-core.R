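mk_matrix <- function(values, platform = "m", kind = "continuous") {
  omics_matrix(values, platform, kind)
}

test_that("sample_universe applies the stated union/intersection ordering", {
  m1 <- mk_matrix(matrix(1:2, 1, 2, dimnames = list("G", c("s1", "s2"))), "a")
  m2 <- mk_matrix(matrix(1:2, 1, 2, dimnames = list("G", c("s2", "s3"))), "b")
  expect_equal(sample_universe(list(m1, m2), "union"), c("s1", "s2", "s3"))
  expect_equal(sample_universe(list(m1, m2), "intersection"), "s2")
  m3 <- mk_matrix(matrix(1, 1, 1, dimnames = list("G", "s9")), "c")
  expect_error(sample_universe(list(m1, m3), "intersection"), "empty")

  set.seed(21)
  mats <- lapply(1:5, function(i)
    random_matrix(2, sample(3:8, 1), platform = paste0("p", i),
                  sample_prefix = sample(c("s", "t"), 1)))
  uni <- sample_universe(mats, "union")
  expect_setequal(uni, unique(unlist(lapply(mats, matrix_samples))))
  expect_false(anyDuplicated(uni) > 0)
})

test_that("single-key ring sort orders values with missing last", {
  m <- mk_matrix(matrix(c(3, 1, 2), 1, 3,
                        dimnames = list("G", c("s1", "s2", "s3"))), "expr")
  key <- sort_key_ring("G", "expr", "ascending")
  expect_equal(sort_samples(c("s1", "s2", "s3"), list(key), list(m)),
               c("s2", "s3", "s1"))
  expect_equal(sort_samples(c("s1", "s2", "s3"),
                            list(sort_key_ring("G", "expr", "descending")),
                            list(m)),
               c("s1", "s3", "s2"))
  m_na <- mk_matrix(matrix(c(NA, 1, 2), 1, 3,
                           dimnames = list("G", c("s1", "s2", "s3"))), "expr")
  expect_equal(sort_samples(c("s1", "s2", "s3"), list(key), list(m_na)),
               c("s2", "s3", "s1"))
  expect_equal(sort_samples(c("s1", "s2", "s3"),
                            list(sort_key_ring("G", "expr", "descending")),
                            list(m_na)),
               c("s3", "s2", "s1"))  # missing still last when descending
})

test_that("multi-key sort is lexicographic with annotation primary", {
  ann <- sample_annotation(c(s1 = "B", s2 = "A", s3 = "A"), "grp")
  m <- mk_matrix(matrix(c(NA, 5, 1), 1, 3,
                        dimnames = list("G", c("s1", "s2", "s3"))), "expr")
  out <- sort_samples(c("s1", "s2", "s3"),
                      list(sort_key_annotation("grp", "ascending"),
                           sort_key_ring("G", "expr", "ascending")),
                      list(m), list(ann))
  expect_equal(out, c("s3", "s2", "s1"))
})

test_that("ties keep the incoming order and unresolvable keys error", {
  m <- mk_matrix(matrix(c(1, 1, 1), 1, 3,
                        dimnames = list("G", c("sB", "sC", "sA"))), "expr")
  key <- list(sort_key_ring("G", "expr", "ascending"))
  expect_equal(sort_samples(c("sB", "sC", "sA"), key, list(m)),
               c("sB", "sC", "sA"))
  expect_error(sort_samples(c("sB"), list(sort_key_ring("NOPE", "expr", "ascending")),
                            list(m)),
               "absent from ring")
  expect_error(sort_samples(c("sB"), list(sort_key_ring("G", "zzz", "ascending")),
                            list(m)),
               "unknown ring")
})

test_that("partition_samples groups by first appearance with unannotated last", {
  ann <- sample_annotation(c(s1 = "X", s2 = "Y", s3 = "X"), "grp")
  p <- partition_samples(c("s1", "s2", "s3"), ann)
  expect_equal(partition_labels(p), c("X", "Y"))
  expect_equal(p[[1]]$samples, c("s1", "s3"))
  expect_equal(p[[2]]$samples, "s2")

  one <- sample_annotation(c(s1 = "X", s2 = "X"), "grp")
  p1 <- partition_samples(c("s1", "s2"), one)
  expect_equal(length(p1), 1L)
  expect_equal(p1[[1]]$samples, c("s1", "s2"))

  holes <- sample_annotation(c(s1 = "X"), "grp")
  p2 <- partition_samples(c("s1", "s2"), holes)
  expect_equal(partition_labels(p2), c("X", "unannotated"))
  expect_equal(p2[[2]]$samples, "s2")

  never <- sample_annotation(c(zz = "X"), "grp")
  expect_error(partition_samples(c("s1", "s2"), never), "covers no sample")
})

test_that("random partitions match brute-force grouping", {
  set.seed(31)
  for (i in 1:10) {
    uni <- sprintf("s%02d", sample(50))
    cats <- sample(c("a", "b", "c", NA), 50, replace = TRUE)
    ann <- sample_annotation(stats::setNames(cats, uni), "grp")
    p <- partition_samples(uni, ann)
    expect_setequal(unlist(lapply(p, `[[`, "samples")), uni)  # union = universe
    expect_false(any(partition_sizes(p) == 0L))
    for (g in p) {
      want <- if (g$label == "unannotated") uni[is.na(annotation_of(ann, uni))]
              else uni[!is.na(annotation_of(ann, uni)) & annotation_of(ann, uni) == g$label]
      expect_equal(g$samples, want)
    }
  }
})

test_that("aggregate_ring takes the mean of non-missing values per group", {
  v <- matrix(c(1, 3, NA, 4), 1, 4,
              dimnames = list("G", c("s1", "s2", "s3", "s4")))
  m <- mk_matrix(v, "expr")
  ann <- sample_annotation(c(s1 = "g1", s2 = "g1", s3 = "g2", s4 = "g2"), "grp")
  p <- partition_samples(c("s1", "s2", "s3", "s4"), ann)
  out <- aggregate_ring(m, "G", p)
  expect_equal(unname(out), c(2, 4))

  allna <- mk_matrix(matrix(NA_real_, 1, 4,
                            dimnames = list("G", c("s1", "s2", "s3", "s4"))), "x")
  expect_true(all(is.na(aggregate_ring(allna, "G", p))))
  expect_error(aggregate_ring(m, "NOPE", p), "absent from matrix")
})

test_that("aggregation is invariant to within-group sample order", {
  set.seed(77)
  m <- random_matrix(3, 20, missing_frac = 0.2)
  uni <- matrix_samples(m)
  cats <- sample(c("a", "b"), 20, replace = TRUE)
  ann <- sample_annotation(stats::setNames(cats, uni), "grp")
  p1 <- partition_samples(uni, ann)
  p2 <- partition_samples(sample(uni), ann)
  # same group labels may appear in different order; compare by label
  a1 <- aggregate_ring(m, "G01", p1)
  a2 <- aggregate_ring(m, "G01", p2)
  expect_equal(a1[sort(names(a1))], a2[sort(names(a2))])
})

test_that("spoke_geometry divides the turn evenly or by weights", {
  g <- spoke_geometry(4)
  expect_equal(g$extent, rep(90, 4))
  expect_equal(g$start, c(0, 90, 180, 270))
  expect_equal(spoke_geometry(1)$extent, 360)
  gw <- spoke_geometry(2, weights = c(3, 1))
  expect_equal(gw$extent, c(270, 90))
  expect_error(spoke_geometry(2, weights = c(1, 0)), "positive")
  expect_error(spoke_geometry(2, weights = c(1, -2)), "positive")
})

test_that("colorize interpolates linearly with clipping and exact midpoint", {
  sc <- color_scale_continuous(-1, 0, 1, low = "#0000FF", midcol = "#FFFFFF",
                               high = "#FF0000")
  expect_equal(colorize(0, sc), "#FFFFFF")
  expect_equal(colorize(-1, sc), "#0000FF")
  expect_equal(colorize(-5, sc), "#0000FF")   # clipped
  expect_equal(colorize(5, sc), "#FF0000")
  # value = (mid+max)/2 -> channel-wise midpoint of mid and high colors
  expect_equal(colorize(0.5, sc), "#FF8080")
  expect_equal(colorize(NA, sc, missing_color = "#ABCDEF"), "#ABCDEF")
  expect_error(color_scale_continuous(1, 0, -1), "min < max")

  bin <- color_scale_binary(low = "#FFFFFF", high = "#000000")
  expect_equal(colorize(0, bin), "#FFFFFF")
  expect_equal(colorize(1, bin), "#000000")
  expect_equal(colorize(0.5, bin), "#808080")  # aggregated fraction
})

test_that("full-mode glyphs map scale endpoints and tolerate absent genes", {
  m <- mk_matrix(matrix(c(-1, 0, 1), 1, 3,
                        dimnames = list("G", c("s1", "s2", "s3"))), "expr")
  sc <- color_scale_continuous(-1, 0, 1, low = "#0000FF", midcol = "#FFFFFF",
                               high = "#FF0000")
  gl <- build_glyph("G", list(ring_spec(m, sc)), order = c("s1", "s2", "s3"))
  expect_equal(gl$rings[[1]]$colors, c("#0000FF", "#FFFFFF", "#FF0000"))
  expect_equal(gl$mode, "full")
  expect_equal(sum(gl$geometry$extent), 360)

  m2 <- mk_matrix(matrix(1, 1, 3, dimnames = list("OTHER", c("s1", "s2", "s3"))),
                  "meth")
  gl2 <- build_glyph("G", list(ring_spec(m, sc), ring_spec(m2)),
                     order = c("s1", "s2", "s3"), missing_color = "#EEEEEE")
  expect_true(all(gl2$rings[[2]]$colors == "#EEEEEE"))  # absent gene: all missing
  expect_false(any(gl2$rings[[1]]$colors == "#EEEEEE"))

  expect_error(build_glyph("G", list(), order = "s1"), "at least one ring")
  expect_error(build_glyph("G", list(ring_spec(m))), "exactly one")
})

test_that("aggregated glyphs carry group means with size-weighted extents", {
  set.seed(13)
  co <- generate_cohort(cohort_spec(n_samples = 60, seed = 13))
  uni <- sample_universe(co$matrices)
  p <- partition_samples(uni, co$annotation)
  gl <- build_glyph("BRAF", lapply(co$matrices, ring_spec), partition = p)
  expect_equal(gl$mode, "aggregated")
  expect_equal(length(gl$rings[[1]]$values), length(p))
  for (ri in seq_along(co$matrices)) {
    vals <- matrix_values(co$matrices[[ri]], "BRAF", uni)
    want <- oracle_group_means(vals, lapply(p, `[[`, "samples"))
    expect_equal(unname(gl$rings[[ri]]$values), unname(want))
  }
  expect_equal(gl$geometry$extent,
               360 * partition_sizes(p) / sum(partition_sizes(p)))
})
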