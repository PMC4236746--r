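# Line-level helpers shared by all text readers/writers. All output files use
# "\n" line endings and UTF-8; node-ID matching is byte-exact everywhere.

kp_read_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  sub("\r$", "", lines)
}

kp_write_lines <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read an undirected interaction network
#'
#' Supports Cytoscape's SIF dialect (`source interaction-type target...`,
#' tab- or whitespace-delimited, one or more targets per line, single-token
#' lines declaring isolated nodes) and plain 2-column tab-separated edge
#' lists. The interaction-type column is ignored: the network is an untyped,
#' undirected simple graph. Self-loops are dropped and duplicate edges
#' collapsed (counts reported via `message()`); isolated nodes are retained
#' with degree 0.
#'
#' @param path Path to the network file.
#' @param format `"sif"`, `"edgelist"`, or `"auto"` (default). Auto-detection
#'   uses the `.sif` extension, then falls back to edge list when every line
#'   has exactly two tab-separated fields.
#' @return An undirected [igraph::igraph] graph with a `name` vertex
#'   attribute.
#' @export
kp_read_network <- function(path, format = c("auto", "sif", "edgelist")) {
  format <- match.arg(format)
  lines <- kp_read_lines(path)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) stop("empty network file: ", path, call. = FALSE)
  if (format == "auto") {
    if (grepl("\\.sif$", path, ignore.case = TRUE)) {
      format <- "sif"
    } else {
      tabs <- lengths(strsplit(lines[keep], "\t", fixed = TRUE))
      format <- if (all(tabs == 2L)) "edgelist" else "sif"
    }
  }
  from <- character(0)
  to <- character(0)
  isolated <- character(0)
  for (i in which(keep)) {
    if (format == "sif") {
      tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
      if (length(tok) == 1L) {
        isolated <- c(isolated, tok)
        next
      }
      if (length(tok) == 2L) {
        stop(path, " line ", i, ": SIF line has an interaction type but no target", call. = FALSE)
      }
      from <- c(from, rep.int(tok[1L], length(tok) - 2L))
      to <- c(to, tok[-(1:2)])
    } else {
      tok <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
      if (length(tok) != 2L || !all(nzchar(tok))) {
        stop(path, " line ", i, ": expected 2 tab-separated columns", call. = FALSE)
      }
      from <- c(from, tok[1L])
      to <- c(to, tok[2L])
    }
  }
  kp_network(from, to, isolated)
}

# Build a simple undirected graph from endpoint vectors, reporting dropped
# self-loops / duplicate edges.
kp_network <- function(from, to, isolated = character(0)) {
  loops <- from == to
  if (any(loops)) {
    message("dropped ", sum(loops), " self-loop(s)")
    isolated <- c(isolated, from[loops])
    from <- from[!loops]
    to <- to[!loops]
  }
  a <- pmin(from, to)
  b <- pmax(from, to)
  dup <- if (length(a)) duplicated(paste0(a, "\r", b)) else logical(0)
  if (any(dup)) message("collapsed ", sum(dup), " duplicate edge(s)")
  nodes <- unique(c(a[!dup], b[!dup], isolated, from, to))
  igraph::graph_from_data_frame(
    data.frame(from = a[!dup], to = b[!dup], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
}

#' Write a network to SIF or edge-list format
#'
#' Edges are written once, endpoint-sorted and line-sorted, so writing is
#' deterministic and `kp_read_network()` round-trips the graph. In SIF mode
#' the interaction type is written as `pp` and isolated nodes as single-token
#' lines; the edge-list format cannot represent isolated nodes (an error is
#' raised if any exist).
#'
#' @param network An undirected igraph graph with named vertices.
#' @param path Output path.
#' @param format `"sif"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
kp_write_network <- function(network, path, format = c("sif", "edgelist")) {
  format <- match.arg(format)
  el <- igraph::as_edgelist(network, names = TRUE)
  a <- pmin(el[, 1L], el[, 2L])
  b <- pmax(el[, 1L], el[, 2L])
  ord <- order(a, b, method = "radix")
  a <- a[ord]
  b <- b[ord]
  iso <- setdiff(igraph::V(network)$name, c(a, b))
  if (format == "sif") {
    lines <- c(paste(a, "pp", b, sep = "\t"), sort(iso, method = "radix"))
  } else {
    if (length(iso)) {
      stop("edge-list format cannot represent ", length(iso), " isolated node(s); use SIF",
           call. = FALSE)
    }
    lines <- paste(a, b, sep = "\t")
  }
  kp_write_lines(lines, path)
}

#' Read a plain-text node list
#'
#' One node ID per line; blank lines and `#` comments are ignored.
#'
#' @param path Path to the list file.
#' @return Character vector of unique node IDs.
#' @export
kp_read_node_list <- function(path) {
  lines <- kp_read_lines(path)
  lines <- trimws(sub("#.*$", "", lines))
  unique(lines[nzchar(lines)])
}

#' Export key pathways as GraphML files plus a JSON summary
#'
#' Writes one GraphML file per pathway (`pathway_001.graphml`, ...) holding
#' the induced subgraph with a boolean `exception` node attribute, and a
#' `pathways.json` summary listing pathways sorted by descending node count
#' (ties broken lexicographically by sorted node IDs).
#'
#' @param pathways List of [kp_pathway] objects.
#' @param network The network the pathways were found on.
#' @param out_dir Output directory (created if missing).
#' @return Character vector of files written, invisibly.
#' @export
kp_write_pathways <- function(pathways, network, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  vn <- igraph::V(network)$name
  for (p in pathways) {
    missing <- setdiff(p$nodes, vn)
    if (length(missing)) {
      stop("pathway node(s) not in network: ", paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  pathways <- kp_sort_pathways(pathways)
  files <- character(0)
  for (i in seq_along(pathways)) {
    p <- pathways[[i]]
    sub <- igraph::induced_subgraph(network, p$nodes)
    igraph::V(sub)$exception <- igraph::V(sub)$name %in% p$exceptions
    f <- file.path(out_dir, sprintf("pathway_%03d.graphml", i))
    igraph::write_graph(sub, f, format = "graphml")
    files <- c(files, f)
  }
  summary <- list(
    n_pathways = length(pathways),
    pathways = lapply(seq_along(pathways), function(i) {
      p <- pathways[[i]]
      list(rank = i, size = p$size, n_exceptions = length(p$exceptions),
           nodes = as.list(p$nodes), exceptions = as.list(p$exceptions))
    }))
  jf <- file.path(out_dir, "pathways.json")
  jsonlite::write_json(summary, jf, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(files, jf))
}

#' Write per-node appearance scores as a Cytoscape-loadable TSV
#'
#' Two tab-separated columns, `node_id` and `score`, sorted by node ID with
#' scores printed at 6 decimal places; a header line is always written. The
#' file loads directly as a Cytoscape node-attribute table for a continuous
#' color mapping.
#'
#' @param scores Named numeric vector of scores, all in `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
kp_write_node_scores <- function(scores, path) {
  if (length(scores) && (anyNA(scores) || any(scores < 0 | scores > 1))) {
    stop("node scores must all lie in [0, 1]", call. = FALSE)
  }
  ids <- sort(names(scores), method = "radix")
  lines <- c("node_id\tscore",
             if (length(ids)) paste0(ids, "\t", sprintf("%.6f", scores[ids])))
  kp_write_lines(lines, path)
}

#' @rdname kp_write_node_scores
#' @export
kp_read_node_scores <- function(path) {
  lines <- kp_read_lines(path)
  if (length(lines) == 0L || lines[1L] != "node_id\tscore") {
    stop("not a node-score table: ", path, call. = FALSE)
  }
  lines <- lines[-1L]
  if (!length(lines)) return(stats::setNames(numeric(0), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(as.numeric(vapply(parts, `[`, "", 2L)),
                  vapply(parts, `[`, "", 1L))
}
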