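# Fixture builders and independent brute-force oracles. The oracles are
# deliberately naive (enumeration, insertion sort, per-edge loops) and share
# no code with the implementation paths they check.

random_matrix <- function(n_genes, n_samples, platform = "m",
                          value_kind = "continuous", missing_frac = 0.1,
                          gene_prefix = "G", sample_prefix = "s") {
  v <- matrix(round(stats::rnorm(n_genes * n_samples), 3), n_genes, n_samples)
  if (missing_frac > 0) {
    idx <- which(stats::runif(length(v)) < missing_frac)
    v[idx] <- NA_real_
  }
  if (value_kind == "binary") v <- (!is.na(v) & v > 0) + 0 * v
  dimnames(v) <- list(sprintf("%s%02d", gene_prefix, seq_len(n_genes)),
                      sprintf("%s%02d", sample_prefix, seq_len(n_samples)))
  omics_matrix(v, platform, value_kind)
}

random_graph <- function(n_nodes, n_edges, track = "t",
                         types = c("activates", "inhibits", "undirected")) {
  nm <- sprintf("N%02d", seq_len(n_nodes))
  from <- sample(nm, n_edges, replace = TRUE)
  to <- sample(nm, n_edges, replace = TRUE)
  type <- sample(types, n_edges, replace = TRUE)
  pathway_graph(data.frame(name = nm, type = "protein"),
                data.frame(from = from, to = to, type = type, track = track))
}

# multiset comparison of edge tables, ignoring row order
edges_equal <- function(a, b) {
  key <- function(e) sort(paste(e$from, e$to, e$type, e$track, sep = "\r"))
  identical(key(a), key(b))
}

# oracle: keep background edges whose endpoints are both selected
oracle_induced <- function(background, members) {
  e <- graph_edges(background)
  keep <- logical(nrow(e))
  for (i in seq_len(nrow(e)))
    keep[i] <- (e$from[i] %in% members) && (e$to[i] %in% members)
  e[keep, , drop = FALSE]
}

# oracle: per-track endpoint filter, re-tagged with the track name
oracle_overlay <- function(display_nodes, tracks) {
  out <- NULL
  for (t in tracks) {
    e <- graph_edges(t$graph)
    for (i in seq_len(nrow(e))) {
      if (e$from[i] %in% display_nodes && e$to[i] %in% display_nodes) {
        row <- e[i, , drop = FALSE]
        row$track <- t$name
        out <- rbind(out, row)
      }
    }
  }
  if (is.null(out)) data.frame(from = character(), to = character(),
                               type = character(), track = character())
  else out
}

# oracle: per-track binary membership sum for a pair
oracle_support <- function(a, b, tracks) {
  n <- 0L
  for (t in tracks) {
    e <- graph_edges(t$graph)
    hit <- FALSE
    for (i in seq_len(nrow(e)))
      if ((e$from[i] == a && e$to[i] == b) || (e$from[i] == b && e$to[i] == a))
        hit <- TRUE
    n <- n + hit
  }
  n
}

# oracle: stable lexicographic multi-key insertion sort; key_cols is a list
# of vectors aligned with `ids` (numeric or character, NA = missing).
# Missing sorts after non-missing under either direction; full ties keep
# input order (stability).
oracle_sort <- function(ids, key_cols, directions) {
  lt <- function(i, j) {           # TRUE iff element i strictly precedes j
    for (k in seq_along(key_cols)) {
      a <- key_cols[[k]][i]; b <- key_cols[[k]][j]
      if (is.na(a) && is.na(b)) next
      if (is.na(a)) return(FALSE)
      if (is.na(b)) return(TRUE)
      if (a == b) next
      asc <- directions[k] == "ascending"
      return(if (asc) a < b else a > b)
    }
    FALSE
  }
  ord <- seq_along(ids)
  for (i in seq_along(ord)[-1L]) {  # stable insertion sort on positions
    j <- i
    while (j > 1L && lt(ord[i], ord[j - 1L])) j <- j - 1L
    ord <- append(ord[-i], ord[i], after = j - 1L)
  }
  ids[ord]
}

# oracle: per-group mean of non-missing values
oracle_group_means <- function(values, groups) {
  vapply(groups, function(g) {
    v <- values[g]
    v <- v[!is.na(v)]
    if (length(v)) sum(v) / length(v) else NA_real_
  }, numeric(1L))
}

count_class <- function(svg, class) {
  length(gregexpr(sprintf('class="%s"', class), svg, fixed = TRUE)[[1L]]) *
    (regexpr(sprintf('class="%s"', class), svg, fixed = TRUE) > 0)
}

toy_render_config <- function(dir, ...) {
  render_config(
    matrices = list(
      list(label = "expression", kind = "continuous", path = file.path(dir, "expression.tsv")),
      list(label = "methylation", kind = "continuous", path = file.path(dir, "methylation.tsv"))
    ),
    networks = list(list(name = "toy_pathway", path = file.path(dir, "pathway.tsv"))),
    genes = file.path(dir, "genes.txt"),
    ...
  )
}
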