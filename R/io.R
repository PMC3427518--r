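#' Read an undirected network from a two-column edge list
#'
#' The only ingest format: plain text, one interaction per line, two
#' whitespace-separated node identifiers.  Lines starting with `#` are
#' comments, except for an optional `#nodes` header (written by
#' [write_edge_list()]) that lists every node identifier in index order so
#' isolated nodes survive a round trip.  Identifiers are mapped to dense
#' indices `1..N` in order of first appearance; duplicate edges are
#' collapsed and self-loops dropped, each with a logged count.
#'
#' @param path Path to the file.
#' @return A [pin_graph] with attribute `node_names` (character vector
#'   mapping index to identifier).
#' @examples
#' f <- tempfile()
#' writeLines(c("a b", "b c"), f)
#' read_edge_list(f)
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty edge-list file: ", path, call. = FALSE)
  header <- character(0)
  hdr <- grepl("^#nodes\\b", lines)
  if (any(hdr)) {
    header <- unlist(strsplit(sub("^#nodes\\s*", "", lines[hdr]), "\\s+"))
    header <- header[nzchar(header)]
  }
  keep <- !grepl("^\\s*(#.*)?$", lines)
  body <- lines[keep]
  lineno <- which(keep)
  if (length(body) == 0L && length(header) == 0L) {
    stop("edge-list file contains no edges and no #nodes header: ", path,
         call. = FALSE)
  }
  toks <- strsplit(trimws(body), "\\s+")
  bad <- which(lengths(toks) != 2L)
  if (length(bad) > 0L) {
    stop("malformed edge-list line ", lineno[bad[1L]], " in ", path, ": '",
         body[bad[1L]], "' (expected two node identifiers)", call. = FALSE)
  }
  a <- vapply(toks, `[`, character(1), 1L)
  b <- vapply(toks, `[`, character(1), 2L)
  names_seen <- unique(c(header, rbind(a, b)))
  ia <- match(a, names_seen)
  ib <- match(b, names_seen)
  self <- ia == ib
  n_self <- sum(self)
  ia <- ia[!self]; ib <- ib[!self]
  lo <- pmin(ia, ib); hi <- pmax(ia, ib)
  key <- (lo - 1) * as.double(length(names_seen)) + hi
  dup <- duplicated(key)
  n_dup <- sum(dup)
  if (n_self > 0L) message("dropped ", n_self, " self-loop(s)")
  if (n_dup > 0L) message("collapsed ", n_dup, " duplicate edge(s)")
  g <- pin_graph(length(names_seen),
                 if (any(!dup)) cbind(lo[!dup], hi[!dup]) else NULL)
  attr(g, "node_names") <- names_seen
  g
}

#' Write a network as a two-column edge list
#'
#' Emits a `#nodes` header naming every node in index order (so node count
#' and isolated nodes survive a round trip through [read_edge_list()])
#' followed by one tab-separated line per edge.
#'
#' @param g A [pin_graph].
#' @param path Output path.
#' @param node_names Optional identifiers per node; defaults to the graph's
#'   `node_names` attribute or `n1..nN`.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path, node_names = NULL) {
  stopifnot(inherits(g, "pin_graph"))
  node_names <- node_names %||% attr(g, "node_names") %||% paste0("n", seq_len(g$n))
  if (length(node_names) != g$n) {
    stop("`node_names` must have one entry per node", call. = FALSE)
  }
  lines <- c(paste(c("#nodes", node_names), collapse = " "),
             paste(node_names[g$edges[, 1L]], node_names[g$edges[, 2L]],
                   sep = "\t"))
  con <- file(path, "wb")   # fixed newline convention => byte-reproducible
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Synthetic benchmark network
#'
#' A reference test case for the inference machinery: a network grown under
#' the DACR model at `delta = 0.4`, `alpha = 0.25`, `p = 0.7`, `m = 3` with
#' a fixed seed, at `5000 / scale` nodes.  `scale = 1` gives the full-size
#' 5000-node network; larger scales give proportionally smaller versions for
#' desk-scale experiments.  The edge count of any one realization is a
#' single stochastic draw, not a calibration constant.
#'
#' @param scale Positive divisor of the 5000-node reference size.
#' @param seed Integer seed (fixed default so fixtures are stable).
#' @return A [pin_graph].
#' @examples
#' make_test_network(scale = 100)   # 50-node miniature
#' @export
make_test_network <- function(scale = 10, seed = 20120220L) {
  if (scale <= 0) stop("`scale` must be positive", call. = FALSE)
  n <- max(10L, as.integer(round(5000 / scale)))
  set.seed(seed)
  grow_dacr(n, delta = 0.4, alpha = 0.25, p = 0.7, m = 3)
}

#' Read or write a run configuration
#'
#' Plain-text YAML round trip for the bundle of choices describing one
#' inference run: data path, candidate models with prior boxes, ABC
#' settings, sampling sizes and the seed.
#'
#' @param path File path.
#' @return `read_run_config()`: a named list; `write_run_config()`: `path`,
#'   invisibly.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg
}

#' @rdname read_run_config
#' @param config A named list (as produced by [read_run_config()] or built
#'   in code).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
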