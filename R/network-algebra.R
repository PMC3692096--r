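#' Ordered set of network tracks
#'
#' A track is one named interaction network drawn in a source-distinguishing
#' color; the list order defines both drawing order and legend order.
#' Default colors follow the convention of showing the first (regulatory)
#' track purple and the second (protein-protein) track brown, then a fixed
#' categorical palette.
#'
#' @param ... tracks, each a list with elements `name`, `graph`
#'   (a [pathway_graph]) and optionally `color`.
#' @return an object of class `track_set`.
#' @export
track_set <- function(...) {
  tracks <- list(...)
  if (length(tracks) == 1L && is.null(tracks[[1L]]$name) && is.list(tracks[[1L]]))
    tracks <- tracks[[1L]]
  nm <- vapply(tracks, function(t) t$name, character(1L))
  if (anyDuplicated(nm))
    stop("duplicate track name: ", nm[duplicated(nm)][1L], call. = FALSE)
  pal <- track_palette(length(tracks))
  tracks <- lapply(seq_along(tracks), function(i) {
    t <- tracks[[i]]
    stopifnot(inherits(t$graph, "pathway_graph"))
    if (is.null(t$color)) t$color <- pal[i]
    t[c("name", "graph", "color")]
  })
  structure(tracks, class = "track_set")
}

#' @rdname track_set
#' @param n number of colors.
#' @export
track_palette <- function(n) {
  pal <- c("#7A28A8", "#8B5A2B", "#1B9E77", "#D95F02", "#7570B3",
           "#E7298A", "#66A61E", "#E6AB02", "#A6761D", "#666666")
  rep_len(pal, max(n, 1L))[seq_len(n)]
}

#' @rdname track_set
#' @param x a `track_set`.
#' @export
track_names <- function(x) vapply(x, function(t) t$name, character(1L))

#' @rdname track_set
#' @export
track_colors <- function(x) {
  stats::setNames(vapply(x, function(t) t$color, character(1L)), track_names(x))
}

#' Filter a background network down to a gene set
#'
#' Returns the induced subgraph of `background` on the intersection of the
#' gene set with the background's nodes: only edges with both endpoints
#' selected survive. This is how a focused subnetwork is pulled out of a
#' large merged background ("SuperPathway") without displaying the whole
#' hairball. With `expand_complexes`, a complex or family node is also
#' retained when it has at least one protein neighbor via
#' `component`/`member` edges and all such neighbors are in the gene set;
#' its structural edges come along. An empty intersection yields an empty
#' graph, not an error.
#'
#' @param background a [pathway_graph].
#' @param genes a [gene_set] or character vector of symbols.
#' @param expand_complexes retain fully-covered complex/family nodes
#'   (default `FALSE`: a complex whose members carry no data would render
#'   as a data-less glyph).
#' @return a [pathway_graph] whose edges are a sub-multiset of the
#'   background's.
#' @export
extract_subnetwork <- function(background, genes, expand_complexes = FALSE) {
  stopifnot(inherits(background, "pathway_graph"))
  members <- if (inherits(genes, "gene_set")) genes$members else as.character(genes)
  nodes <- background$nodes
  edges <- background$edges
  keep <- nodes$name[nodes$name %in% members]
  if (expand_complexes) {
    struct <- edges[edges$type %in% c("component", "member"), , drop = FALSE]
    prot <- nodes$name[nodes$type == "protein"]
    for (cx in nodes$name[nodes$type %in% c("complex", "family")]) {
      nb <- unique(c(struct$from[struct$to == cx], struct$to[struct$from == cx]))
      nb <- intersect(nb, prot)
      if (length(nb) && all(nb %in% members)) keep <- c(keep, cx)
    }
    keep <- unique(keep)
  }
  e_keep <- edges$from %in% keep & edges$to %in% keep
  pathway_graph(nodes[nodes$name %in% keep, , drop = FALSE],
                edges[e_keep, , drop = FALSE])
}

#' Overlay network tracks onto a displayed graph
#'
#' For every track, each edge whose both endpoints are already displayed is
#' added to the graph, tagged with its track name; parallel edges from
#' different tracks stay distinct so each can be drawn in its source color.
#' No new nodes are ever introduced.
#'
#' @param display the currently displayed [pathway_graph].
#' @param tracks a [track_set].
#' @return the augmented [pathway_graph].
#' @export
overlay_tracks <- function(display, tracks) {
  stopifnot(inherits(display, "pathway_graph"))
  if (!inherits(tracks, "track_set")) tracks <- track_set(tracks)
  shown <- display$nodes$name
  edges <- display$edges
  for (t in tracks) {
    te <- t$graph$edges
    hit <- te$from %in% shown & te$to %in% shown
    if (any(hit)) {
      add <- te[hit, , drop = FALSE]
      add$track <- t$name
      edges <- rbind(edges, add)
    }
  }
  pathway_graph(display$nodes, edges)
}

#' Count the tracks supporting a gene pair
#'
#' How many tracks contain any edge (either orientation, any type) between
#' the two genes. A track contributes at most 1 however many edge records
#' it holds for the pair: the count measures independent data sources, the
#' basis for calling a functional linkage high-confidence.
#'
#' @param pair character vector of two gene symbols; order is irrelevant.
#' @param tracks a [track_set].
#' @return integer in `0:length(tracks)`.
#' @export
edge_support <- function(pair, tracks) {
  stopifnot(length(pair) == 2L)
  if (!inherits(tracks, "track_set")) tracks <- track_set(tracks)
  a <- pair[1L]; b <- pair[2L]
  sum(vapply(tracks, function(t) {
    e <- t$graph$edges
    any((e$from == a & e$to == b) | (e$from == b & e$to == a))
  }, logical(1L)))
}
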