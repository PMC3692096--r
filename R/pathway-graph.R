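#' Typed pathway graph
#'
#' Nodes carry an entity type (`protein`, `complex`, `family`,
#' `smallmolecule`, `process`); edges carry an interaction type
#' (`activates`, `inhibits`, `component`, `member`, `undirected`) and the
#' name of the network track they came from. Edges form a multiset:
#' parallel edges from different tracks are kept distinct so the renderer
#' can color each by source. Undirected edges are stored canonically with
#' lexicographically ordered endpoints, so (A,B) and (B,A) are one edge.
#'
#' @param nodes data.frame with columns `name`, `type`.
#' @param edges data.frame with columns `from`, `to`, `type`, `track`.
#' @return an object of class `pathway_graph`.
#' @export
pathway_graph <- function(nodes = data.frame(name = character(), type = character()),
                          edges = data.frame(from = character(), to = character(),
                                             type = character(), track = character())) {
  nodes <- data.frame(name = as.character(nodes$name), type = as.character(nodes$type),
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = as.character(edges$from), to = as.character(edges$to),
                      type = as.character(edges$type), track = as.character(edges$track),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(nodes$name))
    stop("duplicate node name: ", nodes$name[duplicated(nodes$name)][1L], call. = FALSE)
  bad_nt <- setdiff(nodes$type, entity_types())
  if (length(bad_nt))
    stop("unknown entity type: ", bad_nt[1L], call. = FALSE)
  bad_et <- setdiff(edges$type, edge_types())
  if (length(bad_et))
    stop("unknown edge type: ", bad_et[1L], call. = FALSE)
  missing_ep <- setdiff(c(edges$from, edges$to), nodes$name)
  if (length(missing_ep))
    stop("edge references undeclared node: ", missing_ep[1L], call. = FALSE)
  # canonical storage for undirected edges: (A,B) == (B,A)
  flip <- edges$type == "undirected" & edges$from > edges$to
  if (any(flip)) {
    tmp <- edges$from[flip]
    edges$from[flip] <- edges$to[flip]
    edges$to[flip] <- tmp
  }
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "pathway_graph")
}

#' @rdname pathway_graph
#' @export
entity_types <- function() c("protein", "complex", "family", "smallmolecule", "process")

#' @rdname pathway_graph
#' @export
edge_types <- function() c("activates", "inhibits", "component", "member", "undirected")

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("<pathway_graph: %d nodes, %d edges, tracks: %s>\n",
              nrow(x$nodes), nrow(x$edges),
              paste(unique(x$edges$track), collapse = ", ")))
  invisible(x)
}

#' @rdname pathway_graph
#' @param x a `pathway_graph`.
#' @export
graph_nodes <- function(x) x$nodes

#' @rdname pathway_graph
#' @export
graph_edges <- function(x) x$edges

# relation tokens shared by the SIF reader and the typed dialect
.relation_map <- c("pp" = "undirected", "-a>" = "activates", "-t|" = "inhibits",
                   "component>" = "component", "member>" = "member")

.map_relation <- function(token, line_no) {
  if (!token %in% names(.relation_map))
    stop(sprintf("line %d: unknown relation '%s' (expected one of %s)",
                 line_no, token, paste(names(.relation_map), collapse = ", ")),
         call. = FALSE)
  .relation_map[[token]]
}

.relation_token <- function(edge_type) {
  names(.relation_map)[match(edge_type, .relation_map)]
}

#' Read a network in SIF format
#'
#' Each line is `source<TAB>relation<TAB>target`. All nodes default to the
#' `protein` entity type. Relation tokens map to edge types (`pp` is
#' undirected, `-a>` activates, `-t|` inhibits, `component>`/`member>`
#' structural); an unknown relation is an error, never silently undirected,
#' because edge type drives the glyph drawn.
#'
#' @param stream file path or connection.
#' @param track_name track tag attached to every edge.
#' @return a [pathway_graph].
#' @export
read_network_sif <- function(stream, track_name) {
  lines <- .read_text_lines(stream)
  keep <- nzchar(trimws(lines))
  from <- to <- type <- character(0L)
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 3L)
      stop(sprintf("line %d: expected 3 fields, found %d", i, length(f)), call. = FALSE)
    from <- c(from, f[1L])
    to <- c(to, f[3L])
    type <- c(type, .map_relation(f[2L], i))
  }
  node_names <- unique(c(from, to))
  pathway_graph(
    nodes = data.frame(name = node_names, type = rep("protein", length(node_names))),
    edges = data.frame(from = from, to = to, type = type,
                       track = rep(track_name, length(from)))
  )
}

#' @rdname read_network_sif
#' @param x a [pathway_graph]; node typing is dropped on SIF write.
#' @export
write_network_sif <- function(x, stream) {
  stopifnot(inherits(x, "pathway_graph"))
  e <- x$edges
  writeLines(paste(e$from, .relation_token(e$type), e$to, sep = "\t"),
             stream, useBytes = TRUE)
  invisible(x)
}

#' Read a network in the typed-node pathway dialect
#'
#' Node lines `entity_type<TAB>name` declare typed entities and precede
#' edge lines `source<TAB>target<TAB>relation`. Entity types outside the
#' vocabulary, relations outside the vocabulary, and edges referencing
#' undeclared nodes are all errors. The dialect is isolated behind this
#' reader so another pathway format can be added without touching the
#' graph model.
#'
#' @param stream file path or connection.
#' @param track_name track tag attached to every edge.
#' @return a [pathway_graph].
#' @export
read_network_typed <- function(stream, track_name) {
  lines <- .read_text_lines(stream)
  nodes <- data.frame(name = character(), type = character())
  from <- to <- type <- character(0L)
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[i]))) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) == 2L) {
      if (!f[1L] %in% entity_types())
        stop(sprintf("line %d: unknown entity type '%s'", i, f[1L]), call. = FALSE)
      nodes <- rbind(nodes, data.frame(name = f[2L], type = f[1L]))
    } else if (length(f) == 3L) {
      if (!all(c(f[1L], f[2L]) %in% nodes$name)) {
        missing <- setdiff(c(f[1L], f[2L]), nodes$name)
        stop(sprintf("line %d: edge references undeclared node '%s'", i, missing[1L]),
             call. = FALSE)
      }
      from <- c(from, f[1L])
      to <- c(to, f[2L])
      type <- c(type, .map_relation(f[3L], i))
    } else {
      stop(sprintf("line %d: expected 2 (node) or 3 (edge) fields, found %d",
                   i, length(f)), call. = FALSE)
    }
  }
  pathway_graph(nodes,
                data.frame(from = from, to = to, type = type,
                           track = rep(track_name, length(from))))
}

#' @rdname read_network_typed
#' @param x a [pathway_graph].
#' @export
write_network_typed <- function(x, stream) {
  stopifnot(inherits(x, "pathway_graph"))
  n <- x$nodes
  e <- x$edges
  writeLines(c(paste(n$type, n$name, sep = "\t"),
               paste(e$from, e$to, .relation_token(e$type), sep = "\t")),
             stream, useBytes = TRUE)
  invisible(x)
}
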