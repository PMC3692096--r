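#' The shared spoke order of a scene
#'
#' Every ring of every glyph in a scene lays its cells out in this one
#' sample order, so a sample sits at the same angular position everywhere
#' and trends can be traced across the whole pathway.
#'
#' @param matrices list of [omics_matrix] objects.
#' @param policy `"union"`: all samples appearing in any matrix, ordered by
#'   first appearance across the matrices in order; `"intersection"`:
#'   samples present in every matrix, ordered as in the first matrix.
#' @return character vector of sample identifiers (a `sample_order`).
#' @export
sample_universe <- function(matrices, policy = c("union", "intersection")) {
  policy <- match.arg(policy)
  stopifnot(length(matrices) >= 1L)
  sample_lists <- lapply(matrices, matrix_samples)
  if (policy == "union") {
    out <- unique(unlist(sample_lists, use.names = FALSE))
  } else {
    out <- Reduce(intersect, sample_lists[-1L], sample_lists[[1L]])
    if (!length(out)) stop("sample intersection across matrices is empty", call. = FALSE)
  }
  out
}

#' Sort keys for spoke ordering
#'
#' A key either ranks samples by one gene's values in one ring
#' ([sort_key_ring]) or by a sample annotation's categories
#' ([sort_key_annotation]). Keys are applied lexicographically, first key
#' primary — e.g. a phenotype dichotomy as the primary sort and a driver
#' gene's mutation ring as the secondary sort.
#'
#' @param gene gene symbol whose values rank the samples.
#' @param ring platform label of the ring the values come from.
#' @param direction `"ascending"` or `"descending"`.
#' @return an object of class `sort_key`.
#' @export
sort_key_ring <- function(gene, ring, direction = c("ascending", "descending")) {
  direction <- match.arg(direction)
  structure(list(kind = "ring_value", gene = gene, ring = ring, direction = direction),
            class = "sort_key")
}

#' @rdname sort_key_ring
#' @param annotation_name name of the [sample_annotation] to sort by.
#' @export
sort_key_annotation <- function(annotation_name, direction = c("ascending", "descending")) {
  direction <- match.arg(direction)
  structure(list(kind = "annotation", annotation_name = annotation_name,
                 direction = direction),
            class = "sort_key")
}

# resolve one key to a numeric rank vector over the universe; NA -> +Inf so
# missing sorts after everything under either direction
.key_ranks <- function(key, universe, matrices, annotations) {
  if (key$kind == "ring_value") {
    labels <- vapply(matrices, function(m) m$platform, character(1L))
    idx <- match(key$ring, labels)
    if (is.na(idx))
      stop("sort key names unknown ring '", key$ring, "'", call. = FALSE)
    m <- matrices[[idx]]
    if (!key$gene %in% matrix_genes(m))
      stop("sort key gene '", key$gene, "' absent from ring '", key$ring, "'",
           call. = FALSE)
    v <- matrix_values(m, key$gene, universe)
    r <- as.numeric(v)
  } else {
    nm <- vapply(annotations, function(a) a$name, character(1L))
    idx <- match(key$annotation_name, nm)
    if (is.na(idx))
      stop("sort key names unknown annotation '", key$annotation_name, "'",
           call. = FALSE)
    v <- annotation_of(annotations[[idx]], universe)
    r <- xtfrm(v)
  }
  if (key$direction == "descending") r <- -r
  r[is.na(r)] <- Inf
  r
}

#' Sort the sample universe by one or more keys, with propagation
#'
#' Selecting a ring sorts the spokes by that ring's values; because cells
#' are coordinated, the resulting permutation propagates to every other
#' ring of every glyph. The sort is a stable lexicographic multi-key sort:
#' the first key is primary, ties under all keys keep the incoming
#' universe order, and missing values sort after all non-missing values
#' under either direction.
#'
#' @param universe character vector of sample identifiers (the current
#'   order).
#' @param keys list of [sort_key_ring]/[sort_key_annotation] objects;
#'   first is primary.
#' @param matrices list of [omics_matrix] objects the ring keys resolve
#'   against (by platform label).
#' @param annotations list of [sample_annotation] objects the annotation
#'   keys resolve against (by name).
#' @return the permuted universe.
#' @export
sort_samples <- function(universe, keys, matrices = list(), annotations = list()) {
  if (!length(keys)) return(universe)
  if (inherits(keys, "sort_key")) keys <- list(keys)
  ranks <- lapply(keys, .key_ranks, universe = universe,
                  matrices = matrices, annotations = annotations)
  o <- do.call(order, c(ranks, list(method = "radix")))
  universe[o]
}

#' Partition the universe into annotation groups
#'
#' One group per category, in order of the category's first appearance
#' along the universe; samples whose annotation is missing collect into a
#' final group labelled `"unannotated"`. Within each group, samples keep
#' the universe order, so aggregation and the full view stay aligned.
#'
#' @param universe character vector of sample identifiers.
#' @param annotation a [sample_annotation]; it must cover at least one
#'   sample of the universe.
#' @return an object of class `group_partition`: a list of groups, each
#'   `list(label =, samples =)`.
#' @export
partition_samples <- function(universe, annotation) {
  stopifnot(inherits(annotation, "sample_annotation"))
  cats <- annotation_of(annotation, universe)
  if (all(is.na(cats)))
    stop("annotation '", annotation$name, "' covers no sample of the universe",
         call. = FALSE)
  labels <- unique(cats[!is.na(cats)])
  groups <- lapply(labels, function(l) list(label = l, samples = universe[!is.na(cats) & cats == l]))
  if (anyNA(cats))
    groups <- c(groups, list(list(label = "unannotated", samples = universe[is.na(cats)])))
  structure(groups, class = "group_partition")
}

#' @rdname partition_samples
#' @param x a `group_partition`.
#' @export
partition_labels <- function(x) vapply(x, function(g) g$label, character(1L))

#' @rdname partition_samples
#' @export
partition_sizes <- function(x) vapply(x, function(g) length(g$samples), integer(1L))

#' Aggregate one gene's ring into per-group means
#'
#' The arithmetic mean of the non-missing values within each group; a
#' group whose values are all missing yields `NA`. The mean is taken in
#' value space and only then colorized, so an aggregated segment's color
#' is `colorize(mean)`, never a blend of rendered colors. For a binary
#' mutation ring the group mean is the mutation frequency in `[0, 1]`.
#'
#' @param matrix an [omics_matrix]; `gene` must be one of its rows.
#' @param gene gene symbol.
#' @param partition a `group_partition` from [partition_samples].
#' @return named numeric vector of group means, in partition order.
#' @export
aggregate_ring <- function(matrix, gene, partition) {
  stopifnot(inherits(matrix, "omics_matrix"), inherits(partition, "group_partition"))
  if (!gene %in% matrix_genes(matrix))
    stop("gene '", gene, "' absent from matrix '", matrix$platform, "'", call. = FALSE)
  out <- vapply(partition, function(g) {
    v <- matrix_values(matrix, gene, g$samples)
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1L))
  names(out) <- partition_labels(partition)
  out
}

#' Angular geometry of a ring's cells
#'
#' Angles are degrees measured clockwise from 12 o'clock. Unweighted, cell
#' `i` (1-based) starts at `(i-1)/n` of a turn with extent `1/n`; with
#' weights (aggregated mode) the extents are proportional to the weights —
#' group sizes — and always sum to a full turn.
#'
#' @param n_cells number of cells (>= 1).
#' @param weights optional positive weights of length `n_cells`.
#' @return data.frame with columns `start` and `extent` (degrees).
#' @export
spoke_geometry <- function(n_cells, weights = NULL) {
  stopifnot(n_cells >= 1L)
  if (is.null(weights)) weights <- rep(1, n_cells)
  if (length(weights) != n_cells)
    stop("weights must have length n_cells", call. = FALSE)
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must be positive", call. = FALSE)
  extent <- 360 * weights / sum(weights)
  start <- cumsum(c(0, extent[-n_cells]))
  data.frame(start = start, extent = extent)
}

#' Ring specification
#'
#' Binds one platform's matrix to a ring position; list position in
#' [build_glyph] defines radial position, innermost first. A `NULL` scale
#' means [default_scale] of the matrix.
#'
#' @param matrix an [omics_matrix].
#' @param scale optional `color_scale`.
#' @return an object of class `ring_spec`.
#' @export
ring_spec <- function(matrix, scale = NULL) {
  stopifnot(inherits(matrix, "omics_matrix"))
  if (is.null(scale)) scale <- default_scale(matrix)
  stopifnot(inherits(scale, "color_scale"))
  structure(list(matrix = matrix, scale = scale), class = "ring_spec")
}

#' Build a CircleMap glyph for one gene
#'
#' In full mode (an `order` is supplied) every ring holds one cell per
#' universe sample, in universe order, colored through the ring's scale;
#' a gene absent from a ring's matrix yields an all-missing ring, not an
#' error. In aggregated mode (a `partition` is supplied) every ring holds
#' one cell per group, colored by the group mean, with angular extent
#' proportional to group size.
#'
#' @param gene gene symbol.
#' @param rings nonempty list of [ring_spec] objects, innermost first.
#' @param order sample universe (full mode); exactly one of
#'   `order`/`partition` must be given.
#' @param partition a `group_partition` (aggregated mode).
#' @param missing_color color for missing cells.
#' @return an object of class `circlemap_glyph`.
#' @export
build_glyph <- function(gene, rings, order = NULL, partition = NULL,
                        missing_color = "#BBBBBB") {
  if (!length(rings)) stop("glyph needs at least one ring", call. = FALSE)
  if (inherits(rings, "ring_spec")) rings <- list(rings)
  stopifnot(all(vapply(rings, inherits, logical(1L), "ring_spec")))
  if (is.null(order) == is.null(partition))
    stop("supply exactly one of 'order' (full mode) or 'partition' (aggregated mode)",
         call. = FALSE)
  mode <- if (is.null(partition)) "full" else "aggregated"
  if (mode == "full") {
    labels <- order
    geometry <- spoke_geometry(length(labels))
    ring_cells <- lapply(rings, function(rs) {
      v <- matrix_values(rs$matrix, gene, order)
      list(platform = rs$matrix$platform, values = v,
           colors = colorize(v, rs$scale, missing_color))
    })
  } else {
    stopifnot(inherits(partition, "group_partition"))
    labels <- partition_labels(partition)
    geometry <- spoke_geometry(length(partition), weights = partition_sizes(partition))
    ring_cells <- lapply(rings, function(rs) {
      v <- if (gene %in% matrix_genes(rs$matrix)) {
        aggregate_ring(rs$matrix, gene, partition)
      } else {
        stats::setNames(rep(NA_real_, length(partition)), labels)
      }
      list(platform = rs$matrix$platform, values = v,
           colors = colorize(v, rs$scale, missing_color))
    })
  }
  structure(list(gene = gene, mode = mode, cell_labels = labels,
                 geometry = geometry, rings = ring_cells),
            class = "circlemap_glyph")
}

#' @export
print.circlemap_glyph <- function(x, ...) {
  cat(sprintf("<circlemap_glyph %s: %d rings x %d %s cells>\n",
              x$gene, length(x$rings), length(x$cell_labels),
              if (x$mode == "full") "sample" else "group"))
  invisible(x)
}
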