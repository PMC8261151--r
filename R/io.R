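detect_sep <- function(path) {
  l1 <- readLines(path, n = 25L)
  l1 <- l1[!startsWith(l1, "#")][1L]
  if (is.na(l1)) stop("empty file: ", path)
  if (grepl("\t", l1)) "\t" else ","
}

#' Read an ion-count matrix from a wide delimited file
#'
#' Expected layout: a header row of m/z labels, first column of timestamps in
#' seconds. The delimiter (tab or comma) is auto-detected. Empty cells are
#' read as missing values, never as zeros.
#'
#' @param path file path.
#' @param chamber_id label stored on the result (default: file name).
#' @param sep field delimiter; `NULL` (default) auto-detects tab vs comma.
#' @return An [ion_counts] object.
#' @export
read_ion_counts <- function(path, chamber_id = basename(path), sep = NULL) {
  sep <- sep %||% detect_sep(path)
  d <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                         comment.char = "#", na.strings = c("", "NA"))
  if (ncol(d) < 2L) stop("ion-count file needs a time column plus >=1 channel: ", path)
  hdr <- names(d)[-1L]
  if (anyDuplicated(hdr)) stop("duplicate m/z header label: ",
                               paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
  mz <- suppressWarnings(as.numeric(hdr))
  if (anyNA(mz)) stop("non-numeric m/z header label: ",
                      paste(hdr[is.na(mz)], collapse = ", "))
  tm <- d[[1L]]
  if (any(diff(tm) <= 0)) stop("timestamps not strictly increasing in ", path)
  ion_counts(tm, as.matrix(d[-1L]), mz, chamber_id = chamber_id)
}

#' Write an ion-count matrix to a wide delimited file
#'
#' @param x an [ion_counts] object.
#' @param path output path.
#' @param sep field delimiter (tab by default).
#' @return `path`, invisibly.
#' @export
write_ion_counts <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "ion_counts"))
  d <- data.frame(time_s = x$time_s, x$counts, check.names = FALSE)
  utils::write.table(d, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Write / read a flux panel
#'
#' Tab-separated wide format with metadata carried in `#`-prefixed header
#' lines (grid step, wet-up time, compound annotations). `read_panel()` of a
#' `write_panel()` output reproduces the panel to numeric precision.
#'
#' @param panel a [flux_panel].
#' @param path file path.
#' @return `write_panel()` returns `path` invisibly; `read_panel()` a
#'   [flux_panel].
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "flux_panel"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# volnet flux_panel",
               paste0("# wetup_min=", panel$wetup_time),
               paste0("# compound=", paste(panel$compound, collapse = ";"))), con)
  d <- data.frame(time_min = panel$time, phase = panel$phase, panel$values,
                  check.names = FALSE)
  utils::write.table(format(d, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  hdr <- grep("^#", readLines(path, n = 10L), value = TRUE)
  wet <- sub("^# wetup_min=", "", grep("^# wetup_min=", hdr, value = TRUE))
  wet <- if (length(wet) == 1L) suppressWarnings(as.numeric(wet)) else NA_real_
  cmp <- sub("^# compound=", "", grep("^# compound=", hdr, value = TRUE))
  d <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                         comment.char = "#", na.strings = c("", "NA"))
  if (ncol(d) < 3L) stop("panel file has no channels: ", path)
  vals <- as.matrix(d[-(1:2)])
  mz <- as.numeric(names(d)[-(1:2)])
  comp <- if (length(cmp) == 1L) strsplit(cmp, ";", fixed = TRUE)[[1L]] else NULL
  if (!is.null(comp) && length(comp) != length(mz)) comp <- NULL
  flux_panel(d$time_min, vals, mz, compound = comp, wetup_time = wet)
}

#' Read a bipartite metabolite/gene reaction graph
#'
#' A minimal text stand-in for a KEGG reaction-network extraction: one
#' tab-separated file with three sections introduced by `#nodes`, `#edges`
#' and `#pathways` lines. Nodes carry an id, a kind (`metabolite` or `gene`)
#' and a label; edges are directed, each annotated with a reaction id and a
#' comma-separated list of pathway ids; the pathway section maps pathway ids
#' to names. Every edge must join a metabolite and a gene (bipartiteness of
#' the reaction graph), reference existing nodes, and carry known pathway ids.
#'
#' @param path file path.
#' @param manual_edges optional data frame of user-supplied edges (columns
#'   `from`, `to`, optional `reaction`, `pathways`) appended to the graph, for
#'   known reactions missing from the extraction; same bipartiteness rules.
#' @return An object of class `reaction_graph`: list with `graph` (a directed
#'   [igraph::igraph] with vertex attribute `kind` and edge attributes
#'   `reaction`, `pathways`) and `pathways` (data frame `id`, `name`).
#' @export
read_reaction_graph <- function(path, manual_edges = NULL) {
  lines <- readLines(path)
  sec <- cumsum(grepl("^#(nodes|edges|pathways)\\b", lines))
  tags <- lines[grepl("^#(nodes|edges|pathways)\\b", lines)]
  parse_sec <- function(k) {
    body <- lines[sec == k & !grepl("^#", lines)]
    body <- body[nzchar(body)]
    if (length(body) < 2L) return(NULL)
    utils::read.table(text = body, header = TRUE, sep = "\t",
                      check.names = FALSE, colClasses = "character")
  }
  secs <- lapply(seq_along(tags), parse_sec)
  names(secs) <- sub("^#", "", sub("\\s.*$", "", tags))
  nodes <- secs$nodes; edges <- secs$edges; pw <- secs$pathways
  if (is.null(nodes) || is.null(edges)) stop("graph file needs #nodes and #edges sections")
  if (is.null(pw)) pw <- data.frame(id = character(0), name = character(0))
  if (!all(nodes$kind %in% c("metabolite", "gene")))
    stop("node kind must be metabolite or gene")
  if (!is.null(manual_edges)) {
    manual_edges <- as.data.frame(manual_edges)
    if (is.null(manual_edges$reaction)) manual_edges$reaction <- "manual"
    if (is.null(manual_edges$pathways)) manual_edges$pathways <- ""
    edges <- rbind(edges[c("from", "to", "reaction", "pathways")],
                   manual_edges[c("from", "to", "reaction", "pathways")])
  }
  unknown <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(unknown) > 0L)
    stop("edge references unknown node(s): ", paste(unknown, collapse = ", "))
  kind <- stats::setNames(nodes$kind, nodes$id)
  bad <- kind[edges$from] == kind[edges$to]
  if (any(bad))
    stop("bipartiteness violation: edge ", edges$from[which(bad)[1L]], " -> ",
         edges$to[which(bad)[1L]], " joins two ", kind[edges$from[which(bad)[1L]]],
         " nodes")
  pwlists <- strsplit(edges$pathways, ",", fixed = TRUE)
  pwused <- setdiff(unique(unlist(pwlists)), "")
  miss <- setdiff(pwused, pw$id)
  if (length(miss) > 0L)
    stop("edge pathway id(s) absent from #pathways table: ",
         paste(miss, collapse = ", "))
  g <- igraph::graph_from_data_frame(edges[c("from", "to")], directed = TRUE,
                                     vertices = nodes[c("id", "kind", "label")])
  igraph::E(g)$reaction <- edges$reaction
  igraph::E(g)$pathways <- edges$pathways
  structure(list(graph = g, pathways = pw), class = "reaction_graph")
}

#' @export
print.reaction_graph <- function(x, ...) {
  k <- igraph::V(x$graph)$kind
  cat("reaction_graph: ", sum(k == "metabolite"), " metabolites, ",
      sum(k == "gene"), " genes, ", igraph::ecount(x$graph), " edges, ",
      nrow(x$pathways), " pathways\n", sep = "")
  invisible(x)
}

#' Read a channel annotation table and match it to a panel
#'
#' The table maps m/z values to compound names and reaction-graph node ids
#' (a channel may map to several candidate metabolites; ids are
#' comma-separated). Each row is matched to the panel channel closest in m/z
#' within `tol`; unmatched rows and rows without node ids are retained and
#' flagged rather than dropped.
#'
#' @param path tab- or comma-separated file with columns `mz`, `compound`,
#'   `node_ids` and optionally `fragment_of`.
#' @param panel a [flux_panel] to match channels against.
#' @param tol m/z matching tolerance (default 0.005, matching 3-decimal peak
#'   labels).
#' @param graph optional [reaction_graph]; node ids not present in it are
#'   flagged in `unresolved_ids`.
#' @return A data frame of class `channel_annotation` with columns `mz`,
#'   `compound`, `node_ids` (list column), `fragment_of`, `channel` (matched
#'   panel column name or `NA`), `matched`, `projectable`, `unresolved_ids`.
#' @export
read_annotation <- function(path, panel, tol = 0.005, graph = NULL) {
  sep <- detect_sep(path)
  d <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                         comment.char = "#", na.strings = c("", "NA"),
                         colClasses = "character")
  if (!all(c("mz", "compound", "node_ids") %in% names(d)))
    stop("annotation needs columns mz, compound, node_ids")
  mz <- as.numeric(d$mz)
  ids <- lapply(strsplit(ifelse(is.na(d$node_ids), "", d$node_ids), ",", fixed = TRUE),
                function(v) v[nzchar(v)])
  ch <- vapply(mz, function(m) {
    i <- which.min(abs(panel$mz - m))
    if (abs(panel$mz[i] - m) <= tol) colnames(panel$values)[i] else NA_character_
  }, character(1))
  unresolved <- if (is.null(graph)) vapply(ids, function(v) "", character(1)) else
    vapply(ids, function(v)
      paste(setdiff(v, igraph::V(graph$graph)$name), collapse = ","), character(1))
  out <- data.frame(mz = mz, compound = d$compound,
                    fragment_of = if (is.null(d$fragment_of)) NA_character_ else
                      as.numeric(d$fragment_of),
                    channel = ch, matched = !is.na(ch),
                    projectable = lengths(ids) > 0L,
                    unresolved_ids = unresolved)
  out$node_ids <- ids
  if (any(!out$matched))
    message(sum(!out$matched), " annotation row(s) unmatched to any panel channel")
  class(out) <- c("channel_annotation", "data.frame")
  out
}
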