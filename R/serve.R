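#' Answer one CircleMap GET query
#'
#' The pure request handler behind [cm_serve]: given a query string whose
#' parameters mirror the [render_config] fields, it renders the scene and
#' returns the SVG. File parameters are resolved inside `data_dir` only.
#' The body of a 200 response is byte-identical to what [cm_render]
#' produces for the equivalent configuration, so figures can be generated
#' remotely or locally interchangeably.
#'
#' Parameters (repeatable where the config field is): `matrix`
#' (`LABEL:KIND:FILE`), `network` (`NAME:FILE`), `genes` (comma-separated
#' symbols or a gene-set file name), `annotation` (`NAME:FILE`), `sort`
#' (key spec), `group_by`, `mode`, `seed`.
#'
#' @param query the raw query string (everything after `?`).
#' @param data_dir directory the file parameters are resolved against.
#' @return list with elements `status`, `content_type`, `body`. Malformed
#'   parameters give 400; a gene unknown to every matrix and the network
#'   gives 404.
#' @export
handle_get <- function(query, data_dir) {
  params <- .parse_query(query)
  fail <- function(status, msg) list(status = status, content_type = "text/plain",
                                     body = paste0(msg, "\n"))
  safe_path <- function(f) {
    if (grepl("^/", f) || grepl("\\.\\.", f))
      stop("illegal file parameter: ", f, call. = FALSE)
    p <- file.path(data_dir, f)
    if (!file.exists(p)) stop("no such file: ", f, call. = FALSE)
    p
  }
  config <- tryCatch({
    if (is.null(params$matrix)) stop("missing required parameter 'matrix'", call. = FALSE)
    if (is.null(params$network)) stop("missing required parameter 'network'", call. = FALSE)
    if (is.null(params$genes)) stop("missing required parameter 'genes'", call. = FALSE)
    matrices <- lapply(params$matrix, function(s) {
      f <- .split_spec(s, 3L, "matrix parameter (LABEL:KIND:FILE)")
      list(label = f[1L], kind = f[2L], path = safe_path(f[3L]))
    })
    networks <- lapply(params$network, function(s) {
      f <- .split_spec(s, 2L, "network parameter (NAME:FILE)")
      list(name = f[1L], path = safe_path(f[2L]), color = NULL)
    })
    annotations <- lapply(params$annotation, function(s) {
      f <- .split_spec(s, 2L, "annotation parameter (NAME:FILE)")
      list(name = f[1L], path = safe_path(f[2L]))
    })
    genes <- params$genes[1L]
    genes <- if (grepl(",", genes) || !file.exists(file.path(data_dir, genes))) {
      strsplit(genes, ",", fixed = TRUE)[[1L]]
    } else {
      safe_path(genes)
    }
    render_config(matrices = matrices, networks = networks, genes = genes,
                  annotations = annotations,
                  sort = if (is.null(params$sort)) character(0L) else params$sort,
                  group_by = if (is.null(params$group_by)) NULL else params$group_by[1L],
                  mode = if (is.null(params$mode)) "full" else params$mode[1L],
                  seed = if (is.null(params$seed)) 1L else as.integer(params$seed[1L]))
  }, error = function(e) e)
  if (inherits(config, "error")) return(fail(400L, conditionMessage(config)))

  # a gene nobody has heard of -- absent from every matrix and from the
  # background network -- is a lookup failure, not a bad request
  if (is.character(config$genes) && length(config$genes) >= 1L &&
      !file.exists(config$genes[1L])) {
    known <- tryCatch({
      mats <- lapply(config$matrices, function(m) read_matrix(m$path, m$label, m$kind))
      net <- .read_network_any(config$networks[[1L]]$path, config$networks[[1L]]$name)
      unique(c(unlist(lapply(mats, matrix_genes)), net$nodes$name))
    }, error = function(e) NULL)
    if (is.null(known)) return(fail(400L, "cannot read configured data files"))
    unknown <- setdiff(config$genes, known)
    if (length(unknown))
      return(fail(404L, paste0("unknown gene: ", paste(unknown, collapse = ", "))))
  }

  doc <- tryCatch(cm_render(config, quiet = TRUE), error = function(e) e)
  if (inherits(doc, "error")) {
    msg <- conditionMessage(doc)
    status <- if (grepl("0 genes matched", msg)) 404L else 400L
    return(fail(status, msg))
  }
  list(status = 200L, content_type = "image/svg+xml", body = doc)
}

.split_spec <- function(x, n, what) {
  f <- strsplit(x, ":", fixed = TRUE)[[1L]]
  if (length(f) < n)
    stop("malformed ", what, ": '", x, "'", call. = FALSE)
  if (length(f) > n)  # re-join any extra colons into the final field
    f <- c(f[seq_len(n - 1L)], paste(f[seq.int(n, length(f))], collapse = ":"))
  f
}

.parse_query <- function(query) {
  query <- sub("^\\?", "", query)
  out <- list()
  if (!nzchar(query)) return(out)
  for (kv in strsplit(query, "&", fixed = TRUE)[[1L]]) {
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0L) next
    k <- substr(kv, 1L, eq - 1L)
    v <- utils::URLdecode(chartr("+", " ", substr(kv, eq + 1L, nchar(kv))))
    out[[k]] <- c(out[[k]], v)
  }
  out
}

#' Serve CircleMaps over HTTP GET
#'
#' A minimal, read-only, single-threaded HTTP server over a preloaded data
#' directory: `GET /render?...` (parameters as in [handle_get]) returns an
#' `image/svg+xml` document identical to the equivalent [cm_render] call;
#' `GET /` returns a short usage text. There are no uploads and no
#' sessions. Intended for figure generation on a trusted local interface,
#' not for the open internet.
#'
#' @param data_dir directory whose files the query parameters may name.
#' @param port TCP port.
#' @param host interface to bind (default loopback).
#' @param max_requests stop after this many requests (mainly for tests);
#'   `Inf` serves until interrupted.
#' @param quiet suppress per-request log lines.
#' @return invisibly, the number of requests served.
#' @export
cm_serve <- function(data_dir, port = 8765L, host = "127.0.0.1",
                     max_requests = Inf, quiet = FALSE) {
  stopifnot(dir.exists(data_dir))
  srv <- serverSocket(port)
  on.exit(close(srv), add = TRUE)
  if (!quiet) message("circlemapr: serving ", data_dir, " on http://", host, ":", port)
  served <- 0L
  while (served < max_requests) {
    con <- socketAccept(srv, blocking = TRUE, open = "r+b", timeout = 60)
    served <- served + 1L
    tryCatch({
      req <- readLines(con, n = 1L, warn = FALSE)
      repeat {  # drain headers
        h <- readLines(con, n = 1L, warn = FALSE)
        if (!length(h) || !nzchar(sub("\r$", "", h))) break
      }
      target <- strsplit(req, " ", fixed = TRUE)[[1L]][2L]
      if (is.na(target)) target <- "/"
      res <- if (startsWith(target, "/render")) {
        q <- sub("^/render\\??", "", target)
        handle_get(q, data_dir)
      } else if (target == "/" || startsWith(target, "/?")) {
        list(status = 200L, content_type = "text/plain",
             body = "circlemapr render service; GET /render?matrix=LABEL:KIND:FILE&network=NAME:FILE&genes=G1,G2...\n")
      } else {
        list(status = 404L, content_type = "text/plain", body = "not found\n")
      }
      reason <- c("200" = "OK", "400" = "Bad Request", "404" = "Not Found")
      body <- charToRaw(res$body)
      head <- paste0("HTTP/1.1 ", res$status, " ", reason[as.character(res$status)],
                     "\r\nContent-Type: ", res$content_type,
                     "\r\nContent-Length: ", length(body),
                     "\r\nConnection: close\r\n\r\n")
      writeBin(c(charToRaw(head), body), con)
      if (!quiet) message("circlemapr: ", res$status, " ", target)
    }, error = function(e) {
      if (!quiet) message("circlemapr: request failed: ", conditionMessage(e))
    }, finally = close(con))
  }
  invisible(served)
}
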