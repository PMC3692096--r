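#' Render configuration
#'
#' One declarative description of a rendering job: which matrices form the
#' rings (in inner-to-outer order), which networks form the background and
#' the overlay tracks, which genes to display, how to sort or group the
#' spokes, and the layout seed. [validate_config] rejects every invariant
#' violation before any rendering work starts.
#'
#' @param matrices list of `list(label, kind, path)` ring sources, inner
#'   ring first; labels must be unique.
#' @param networks list of `list(name, path, color = NULL)`; the first
#'   network is the background the gene set filters, and every network is
#'   also an overlay track drawn in its own color. Files ending in `.sif`
#'   are read as SIF, anything else as the typed-node dialect.
#' @param genes path to a gene-set file, or a character vector of symbols.
#' @param annotations list of `list(name, path)` sample annotation tables.
#' @param sort character vector of key specs (`"ring:GENE:PLATFORM[:asc|desc]"`
#'   or `"annot:NAME[:asc|desc]"`), primary first, or a list of
#'   [sort_key_ring]/[sort_key_annotation] objects.
#' @param group_by annotation name to aggregate by (required when
#'   `mode = "aggregated"`).
#' @param mode `"full"` (one spoke per sample) or `"aggregated"` (one
#'   segment per group).
#' @param seed layout seed.
#' @param expand_complexes passed to [extract_subnetwork].
#' @param scene a [scene_config].
#' @return a list of class `render_config`.
#' @export
render_config <- function(matrices, networks, genes, annotations = list(),
                          sort = character(0L), group_by = NULL,
                          mode = c("full", "aggregated"), seed = 1L,
                          expand_complexes = FALSE, scene = scene_config()) {
  mode <- match.arg(mode)
  structure(list(matrices = matrices, networks = networks, genes = genes,
                 annotations = annotations, sort = sort, group_by = group_by,
                 mode = mode, seed = as.integer(seed),
                 expand_complexes = isTRUE(expand_complexes), scene = scene),
            class = "render_config")
}

#' Parse a sort key spec string
#'
#' `"ring:BRAF:mutation:desc"` sorts by BRAF's values in the mutation
#' ring, descending; `"annot:hypermutated"` sorts by the hypermutated
#' annotation, ascending by default.
#'
#' @param spec key spec string.
#' @return a `sort_key`.
#' @export
parse_sort_key <- function(spec) {
  f <- strsplit(spec, ":", fixed = TRUE)[[1L]]
  dir_of <- function(tok) {
    if (is.na(tok) || tok == "asc") "ascending"
    else if (tok == "desc") "descending"
    else stop("sort key '", spec, "': direction must be 'asc' or 'desc'", call. = FALSE)
  }
  if (f[1L] == "ring") {
    if (length(f) < 3L || length(f) > 4L)
      stop("sort key '", spec, "': expected ring:GENE:PLATFORM[:asc|desc]", call. = FALSE)
    sort_key_ring(f[2L], f[3L], dir_of(f[4L]))
  } else if (f[1L] == "annot") {
    if (length(f) < 2L || length(f) > 3L)
      stop("sort key '", spec, "': expected annot:NAME[:asc|desc]", call. = FALSE)
    sort_key_annotation(f[2L], dir_of(f[3L]))
  } else {
    stop("sort key '", spec, "': kind must be 'ring' or 'annot'", call. = FALSE)
  }
}

#' @rdname render_config
#' @param config a `render_config`.
#' @param check_files also require every referenced file to be readable.
#' @return `validate_config` returns the config invisibly or throws.
#' @export
validate_config <- function(config, check_files = TRUE) {
  stopifnot(inherits(config, "render_config"))
  if (!length(config$matrices)) stop("no matrices configured", call. = FALSE)
  if (!length(config$networks)) stop("no networks configured", call. = FALSE)
  labels <- vapply(config$matrices, function(m) m$label, character(1L))
  if (anyDuplicated(labels))
    stop("duplicate ring label: ", labels[duplicated(labels)][1L], call. = FALSE)
  kinds <- vapply(config$matrices, function(m) m$kind, character(1L))
  bad <- setdiff(kinds, c("continuous", "discrete", "binary"))
  if (length(bad)) stop("unknown value kind: ", bad[1L], call. = FALSE)
  nn <- vapply(config$networks, function(x) x$name, character(1L))
  if (anyDuplicated(nn))
    stop("duplicate track name: ", nn[duplicated(nn)][1L], call. = FALSE)
  if (config$mode == "aggregated" && is.null(config$group_by))
    stop("aggregated mode requires 'group_by'", call. = FALSE)
  if (!is.null(config$group_by)) {
    an <- vapply(config$annotations, function(a) a$name, character(1L))
    if (!config$group_by %in% an)
      stop("group_by names unknown annotation '", config$group_by, "'", call. = FALSE)
  }
  if (is.character(config$sort)) lapply(config$sort, parse_sort_key)
  if (check_files) {
    paths <- c(vapply(config$matrices, function(m) m$path, character(1L)),
               vapply(config$networks, function(x) x$path, character(1L)),
               if (is.character(config$genes) && length(config$genes) == 1L &&
                   file.exists(config$genes)) config$genes,
               vapply(config$annotations, function(a) a$path, character(1L)))
    for (p in paths)
      if (!file.exists(p)) stop("cannot read file: ", p, call. = FALSE)
  }
  invisible(config)
}

.read_network_any <- function(path, track_name) {
  if (grepl("\\.sif$", path, ignore.case = TRUE)) read_network_sif(path, track_name)
  else read_network_typed(path, track_name)
}

#' Run the full rendering pipeline
#'
#' Read everything, filter the background network to the gene set, overlay
#' the remaining tracks, build the shared sample order (sorted by the
#' configured keys) or group partition, build one CircleMap glyph per
#' displayed gene with data, lay the graph out, and serialize the scene to
#' SVG. Progress counts (genes matched, samples in universe, edges
#' displayed) go to the message stream unless `quiet`.
#'
#' @param config a [render_config].
#' @param out optional output file path.
#' @param quiet suppress progress messages.
#' @return invisibly, the SVG document as one string.
#' @export
cm_render <- function(config, out = NULL, quiet = FALSE) {
  validate_config(config)
  say <- function(...) if (!quiet) message("circlemapr: ", ...)

  matrices <- lapply(config$matrices, function(m)
    read_matrix(m$path, m$label, m$kind))
  networks <- lapply(config$networks, function(x)
    .read_network_any(x$path, x$name))
  gset <- if (is.character(config$genes) && length(config$genes) == 1L &&
              file.exists(config$genes)) {
    read_gene_set(config$genes)
  } else {
    gene_set(config$genes, "query")
  }
  annotations <- lapply(config$annotations, function(a)
    read_annotation(a$path, a$name))

  display <- extract_subnetwork(networks[[1L]], gset,
                                expand_complexes = config$expand_complexes)
  n_matched <- sum(display$nodes$name %in% gset$members)
  say(n_matched, " genes matched")
  if (n_matched == 0L)
    stop("0 genes matched: gene set shares no symbol with the background network",
         call. = FALSE)
  if (length(networks) > 1L) {
    tracks <- track_set(lapply(seq_along(networks)[-1L], function(i) {
      list(name = config$networks[[i]]$name, graph = networks[[i]],
           color = config$networks[[i]]$color)
    }))
    display <- overlay_tracks(display, tracks)
  }
  say(nrow(display$edges), " edges displayed")

  universe <- sample_universe(matrices, "union")
  say(length(universe), " samples in universe")
  keys <- if (is.character(config$sort)) lapply(config$sort, parse_sort_key)
          else config$sort
  if (length(keys))
    universe <- sort_samples(universe, keys, matrices, annotations)

  partition <- NULL
  if (config$mode == "aggregated") {
    an <- vapply(annotations, function(a) a$name, character(1L))
    partition <- partition_samples(universe, annotations[[match(config$group_by, an)]])
    say(length(partition), " sample groups")
  }

  rings <- lapply(matrices, ring_spec)
  with_data <- vapply(display$nodes$name, function(g)
    any(vapply(matrices, function(m) g %in% matrix_genes(m), logical(1L))),
    logical(1L))
  glyph_genes <- display$nodes$name[display$nodes$type == "protein" & with_data]
  glyphs <- stats::setNames(lapply(glyph_genes, function(g) {
    if (config$mode == "full")
      build_glyph(g, rings, order = universe,
                  missing_color = config$scene$missing_color)
    else
      build_glyph(g, rings, partition = partition,
                  missing_color = config$scene$missing_color)
  }), glyph_genes)

  cols <- track_palette(length(networks))
  user_cols <- vapply(config$networks, function(x)
    if (is.null(x$color)) NA_character_ else x$color, character(1L))
  cols[!is.na(user_cols)] <- user_cols[!is.na(user_cols)]
  names(cols) <- vapply(config$networks, function(x) x$name, character(1L))

  layout <- layout_graph(display, seed = config$seed, config = config$scene)
  scene <- assemble_scene(display, glyphs, layout, cols, config$scene)
  doc <- write_svg(scene, out)
  if (!is.null(out)) say("wrote ", out)
  invisible(doc)
}
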