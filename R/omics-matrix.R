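#' Gene-by-sample score matrix for one measurement platform
#'
#' The container for one platform's worth of omics data: a numeric matrix
#' whose rows are genes (HUGO-style symbols) and whose columns are samples.
#' Missing measurements are stored as `NA`.
#'
#' @param values numeric matrix with unique rownames (genes) and unique
#'   colnames (samples); `NA` marks missing values.
#' @param platform short label for the platform (e.g. `"expression"`);
#'   this is the name rings are addressed by.
#' @param value_kind one of `"continuous"`, `"discrete"`, `"binary"`.
#'   Binary matrices may only hold 0, 1 and `NA`.
#' @return an object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, platform, value_kind = c("continuous", "discrete", "binary")) {
  value_kind <- match.arg(value_kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || is.null(samples))
    stop("'values' must carry gene rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(genes))
    stop("duplicate gene symbol: ", genes[duplicated(genes)][1L], call. = FALSE)
  if (anyDuplicated(samples))
    stop("duplicate sample identifier: ", samples[duplicated(samples)][1L], call. = FALSE)
  if (ncol(values) == 0L)
    stop("matrix has zero samples", call. = FALSE)
  if (value_kind == "binary") {
    v <- values[!is.na(values)]
    if (length(v) && !all(v %in% c(0, 1)))
      stop("binary matrix contains values outside {0, 1}", call. = FALSE)
  }
  structure(
    list(platform = as.character(platform), value_kind = value_kind, values = values),
    class = "omics_matrix"
  )
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix '%s' (%s): %d genes x %d samples>\n",
              x$platform, x$value_kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @rdname omics_matrix
#' @param x an `omics_matrix`.
#' @export
matrix_genes <- function(x) rownames(x$values)

#' @rdname omics_matrix
#' @export
matrix_samples <- function(x) colnames(x$values)

#' Look up one gene's values over a set of samples
#'
#' Samples absent from the matrix, and the whole row when the gene itself
#' is absent, come back as `NA`: a gene missing from one platform is data
#' absence, not an error, at this level.
#'
#' @param x an `omics_matrix`.
#' @param gene gene symbol (exact, case-sensitive).
#' @param samples character vector of sample identifiers.
#' @return named numeric vector along `samples`.
#' @export
matrix_values <- function(x, gene, samples) {
  out <- rep(NA_real_, length(samples))
  names(out) <- samples
  if (gene %in% rownames(x$values)) {
    hit <- samples %in% colnames(x$values)
    out[hit] <- x$values[gene, samples[hit]]
  }
  out
}

# tokens accepted as missing on read; written back as "NA"
.missing_tokens <- c("NA", "nan", "NaN", "")

.read_text_lines <- function(stream) {
  lines <- readLines(stream, warn = FALSE, encoding = "UTF-8")
  sub("\r$", "", lines)
}

.parse_score <- function(token, line_no) {
  if (token %in% .missing_tokens) return(NA_real_)
  v <- suppressWarnings(as.numeric(token))
  if (is.na(v))
    stop(sprintf("line %d: cannot parse value '%s' as a number", line_no, token),
         call. = FALSE)
  v
}

#' Read a tab-separated gene-by-sample score matrix
#'
#' The first row lists sample identifiers (its first field is an ignored
#' corner label), the first column of every subsequent row is the gene
#' symbol. Tokens `NA`, `nan`, `NaN` and empty fields parse to missing.
#' Ragged rows and duplicate gene rows are errors, never silently fixed.
#'
#' @param stream file path or connection.
#' @param platform_label platform name to attach to the matrix.
#' @param value_kind `"continuous"`, `"discrete"` or `"binary"`.
#' @return an [omics_matrix].
#' @export
read_matrix <- function(stream, platform_label,
                        value_kind = c("continuous", "discrete", "binary")) {
  value_kind <- match.arg(value_kind)
  lines <- .read_text_lines(stream)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop("matrix file needs a header line and at least one data row", call. = FALSE)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L)
    stop("matrix file has zero sample columns", call. = FALSE)
  samples <- header[-1L]
  n_s <- length(samples)
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  genes <- character(length(rows))
  values <- matrix(NA_real_, nrow = length(rows), ncol = n_s)
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    # a trailing empty field is dropped by strsplit; restore it
    if (length(f) == n_s && grepl("\t$", lines[i + 1L])) f <- c(f, "")
    if (length(f) != n_s + 1L)
      stop(sprintf("line %d: expected %d fields, found %d", i + 1L, n_s + 1L, length(f)),
           call. = FALSE)
    genes[i] <- f[1L]
    values[i, ] <- vapply(f[-1L], .parse_score, numeric(1L), line_no = i + 1L)
  }
  if (anyDuplicated(genes))
    stop("duplicate gene symbol: ", genes[duplicated(genes)][1L], call. = FALSE)
  dimnames(values) <- list(genes, samples)
  omics_matrix(values, platform_label, value_kind)
}

#' Write an omics matrix as tab-separated text
#'
#' Missing values are written as `NA`; [read_matrix] recovers the grid
#' exactly.
#'
#' @param x an [omics_matrix].
#' @param stream file path or connection.
#' @export
write_matrix <- function(x, stream) {
  stopifnot(inherits(x, "omics_matrix"))
  vals <- x$values
  body <- apply(vals, 1L, function(r) {
    paste(ifelse(is.na(r), "NA", formatC(r, format = "g", digits = 17)), collapse = "\t")
  })
  lines <- c(
    paste(c("gene", colnames(vals)), collapse = "\t"),
    paste(rownames(vals), body, sep = "\t")
  )
  writeLines(lines, stream, useBytes = TRUE)
  invisible(x)
}

#' Sample annotation: a named categorical labelling of samples
#'
#' @param assignments named character vector mapping sample identifier to
#'   category; `NA` marks an unannotated sample.
#' @param name label of the annotation (e.g. `"hypermutated"`).
#' @return an object of class `sample_annotation`.
#' @export
sample_annotation <- function(assignments, name) {
  if (is.null(names(assignments)) || any(!nzchar(names(assignments))))
    stop("assignments must be a named vector keyed by sample identifier", call. = FALSE)
  if (anyDuplicated(names(assignments)))
    stop("duplicate sample identifier in annotation", call. = FALSE)
  structure(list(name = as.character(name),
                 assignments = vapply(assignments, as.character, character(1L))),
            class = "sample_annotation")
}

#' Look up the category of samples under an annotation
#'
#' @param x a [sample_annotation].
#' @param samples sample identifiers; samples the annotation has never seen
#'   resolve to `NA`.
#' @return character vector along `samples`.
#' @export
annotation_of <- function(x, samples) {
  out <- rep(NA_character_, length(samples))
  names(out) <- samples
  hit <- samples %in% names(x$assignments)
  out[hit] <- x$assignments[samples[hit]]
  out
}

#' Read a two-column sample annotation table
#'
#' Each line is `sample<TAB>category`; an optional header whose first field
#' is `sample` is skipped. An empty category field marks the sample
#' unannotated. A sample listed twice with conflicting categories is an
#' error.
#'
#' @param stream file path or connection.
#' @param name annotation label; defaults to the stream's file name.
#' @return a [sample_annotation].
#' @export
read_annotation <- function(stream, name = NULL) {
  if (is.null(name))
    name <- if (is.character(stream)) sub("\\.[^.]*$", "", basename(stream)) else "annotation"
  lines <- .read_text_lines(stream)
  lines <- lines[nzchar(lines)]
  if (length(lines) && tolower(strsplit(lines[1L], "\t", fixed = TRUE)[[1L]][1L]) == "sample")
    lines <- lines[-1L]
  out <- character(0L)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) == 1L) f <- c(f, "")
    if (length(f) != 2L)
      stop(sprintf("line %d: expected 2 fields, found %d", i, length(f)), call. = FALSE)
    cat_i <- if (nzchar(f[2L])) f[2L] else NA_character_
    if (f[1L] %in% names(out)) {
      prev <- out[[f[1L]]]
      if (!identical(prev, cat_i) && !(is.na(prev) && is.na(cat_i)))
        stop(sprintf("line %d: sample '%s' re-assigned from '%s' to '%s'",
                     i, f[1L], prev, cat_i), call. = FALSE)
    } else {
      out[[f[1L]]] <- cat_i
    }
  }
  sample_annotation(out, name)
}

#' @rdname read_annotation
#' @param x a [sample_annotation].
#' @export
write_annotation <- function(x, stream) {
  stopifnot(inherits(x, "sample_annotation"))
  a <- x$assignments
  writeLines(c("sample\tcategory",
               paste(names(a), ifelse(is.na(a), "", a), sep = "\t")),
             stream, useBytes = TRUE)
  invisible(x)
}

#' Gene set: an ordered list of gene symbols
#'
#' @param members character vector of symbols; duplicates collapsed keeping
#'   the first occurrence.
#' @param name set label.
#' @return an object of class `gene_set`.
#' @export
gene_set <- function(members, name = "gene_set") {
  members <- as.character(members)
  if (!length(members)) stop("gene set is empty", call. = FALSE)
  structure(list(name = as.character(name), members = members[!duplicated(members)]),
            class = "gene_set")
}

#' Read a gene set, one symbol per line
#'
#' Lines starting with `#` are comments; blank lines are skipped;
#' duplicates collapse keeping the first occurrence, preserving file order.
#' An empty file is an error.
#'
#' @param stream file path or connection.
#' @param name set label; defaults to the file name.
#' @return a [gene_set].
#' @export
read_gene_set <- function(stream, name = NULL) {
  if (is.null(name))
    name <- if (is.character(stream)) sub("\\.[^.]*$", "", basename(stream)) else "gene_set"
  lines <- trimws(.read_text_lines(stream))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("gene set file contains no symbols", call. = FALSE)
  gene_set(lines, name)
}

#' @rdname read_gene_set
#' @param x a [gene_set].
#' @export
write_gene_set <- function(x, stream) {
  stopifnot(inherits(x, "gene_set"))
  writeLines(x$members, stream, useBytes = TRUE)
  invisible(x)
}
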