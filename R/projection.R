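#' Project a connection onto the reaction graph as a shortest path
#'
#' Maps a source-target mVC connection to a shortest directed path between
#' their annotated metabolite nodes (breadth-first search, unit edge
#' weights). When a channel is annotated with several candidate metabolites,
#' the (source id, target id) combination giving the globally shortest path
#' wins; equal-length paths are tie-broken by lexicographic node-id sequence,
#' so projection is deterministic. Connections with no directed path (or
#' unannotated endpoints) are kept and flagged unprojectable rather than
#' dropped.
#'
#' @param connection list or one-row data frame with `source` and `target`
#'   channel labels (and optionally an identifying `id`).
#' @param annotation a [read_annotation()] table.
#' @param graph a [reaction_graph].
#' @return A list of class `projected_path`: `source`, `target`, `status`
#'   (`"projected"` or `"unprojectable"`), `reason`, `nodes` (ordered id
#'   sequence, alternating metabolite/gene), `length` (edge count), and
#'   `pathways` (pathway ids on traversed edges).
#' @export
project_connection <- function(connection, annotation, graph) {
  src_ids <- annotation_ids(annotation, connection$source)
  tgt_ids <- annotation_ids(annotation, connection$target)
  base <- list(source = connection$source, target = connection$target,
               nodes = character(0), length = NA_integer_,
               pathways = character(0))
  if (length(src_ids) == 0L || length(tgt_ids) == 0L) {
    base$status <- "unprojectable"
    base$reason <- paste0("unannotated ",
                          paste(c("source", "target")[c(length(src_ids) == 0L,
                                                        length(tgt_ids) == 0L)],
                                collapse = " and "))
    return(structure(base, class = "projected_path"))
  }
  g <- graph$graph
  known <- igraph::V(g)$name
  best <- NULL
  for (s in intersect(src_ids, known)) for (t in intersect(tgt_ids, known)) {
    if (s == t) next
    sp <- igraph::all_shortest_paths(g, from = s, to = t, mode = "out")$vpaths
    if (length(sp) == 0L) next
    seqs <- lapply(sp, function(v) igraph::V(g)$name[v])
    # deterministic tie-break: lexicographically smallest node-id sequence
    key <- vapply(seqs, paste, character(1), collapse = "\r")
    cand <- seqs[[order(key)[1L]]]
    if (is.null(best) || length(cand) < length(best) ||
        (length(cand) == length(best) &&
         paste(cand, collapse = "\r") < paste(best, collapse = "\r")))
      best <- cand
  }
  if (is.null(best)) {
    base$status <- "unprojectable"
    base$reason <- "no directed path in reaction graph"
    return(structure(base, class = "projected_path"))
  }
  eids <- igraph::get_edge_ids(g, rbind(best[-length(best)], best[-1L]))
  pw <- setdiff(unique(unlist(strsplit(igraph::E(g)$pathways[eids], ",",
                                       fixed = TRUE))), "")
  base$status <- "projected"; base$reason <- NA_character_
  base$nodes <- best; base$length <- length(best) - 1L; base$pathways <- pw
  structure(base, class = "projected_path")
}

annotation_ids <- function(annotation, channel) {
  i <- which(annotation$channel == channel)
  if (length(i) == 0L) return(character(0))
  unique(unlist(annotation$node_ids[i]))
}

#' @export
print.projected_path <- function(x, ...) {
  if (x$status == "projected")
    cat("path ", x$source, " -> ", x$target, " (", x$length, " edges): ",
        paste(x$nodes, collapse = " -> "), "\n", sep = "")
  else
    cat("unprojectable ", x$source, " -> ", x$target, ": ", x$reason, "\n",
        sep = "")
  invisible(x)
}

#' Project every retained connection and triad of a network
#'
#' Pairwise connections project source to target; each synergy triad projects
#' its two sources to the shared target independently (the "forked" pair of
#' paths).
#'
#' @param net an `mvc_network` (uses `net$top` and `net$triads`).
#' @param annotation a [read_annotation()] table.
#' @param graph a [reaction_graph].
#' @return A list of `projected_path` objects; each carries an `origin`
#'   attribute (`"pair"` or `"triad"`).
#' @export
project_network <- function(net, annotation, graph) {
  paths <- list()
  d <- net$top
  for (k in seq_len(nrow(d))) {
    pp <- project_connection(d[k, ], annotation, graph)
    attr(pp, "origin") <- "pair"
    paths[[length(paths) + 1L]] <- pp
  }
  tr <- net$triads
  if (!is.null(tr)) {
    keep <- paste(tr$source1, tr$target) %in% paste(d$source, d$target)
    tr <- tr[keep, , drop = FALSE]
    for (k in seq_len(nrow(tr))) {
      for (srccol in c("source1", "source2")) {
        pp <- project_connection(list(source = tr[[srccol]][k],
                                      target = tr$target[k]),
                                 annotation, graph)
        attr(pp, "origin") <- "triad"
        paths[[length(paths) + 1L]] <- pp
      }
    }
  }
  paths
}

#' Extract pathway sub-networks supported by at least two connections
#'
#' A projected path is a member of a pathway when at least one of its edges
#' carries that pathway's id; pathways with at least `min_members` member
#' paths are emitted with the subgraph induced by their members' nodes and
#' edges. A path crossing several pathways counts once for each.
#'
#' @param paths list of `projected_path` objects.
#' @param graph a [reaction_graph].
#' @param min_members minimum member paths (default 2).
#' @return A list of sub-networks, each a list with `pathway_id`,
#'   `pathway_name`, `n_members`, `members` (the member paths), and `graph`
#'   (induced igraph). Sorted by pathway id, so the result is
#'   order-independent.
#' @export
extract_subnetworks <- function(paths, graph, min_members = 2L) {
  proj <- Filter(function(p) p$status == "projected", paths)
  if (length(proj) == 0L) return(list())
  membership <- lapply(proj, `[[`, "pathways")
  counts <- table(unlist(membership))
  ids <- sort(names(counts)[counts >= min_members])
  lapply(ids, function(pid) {
    mem <- proj[vapply(membership, function(pw) pid %in% pw, logical(1))]
    nodes <- unique(unlist(lapply(mem, `[[`, "nodes")))
    g <- igraph::induced_subgraph(graph$graph, nodes)
    nm <- graph$pathways$name[match(pid, graph$pathways$id)]
    list(pathway_id = pid, pathway_name = nm, n_members = length(mem),
         members = mem, graph = g)
  })
}

#' Export projected sub-networks and paths
#'
#' Writes a GraphML file of the union of projected paths (node attributes:
#' `kind`, and `detected` flagging metabolites measured as volatile
#' channels), a flat edge table, a sub-network table, and the unprojectable
#' connections with reasons.
#'
#' @param subnetworks result of [extract_subnetworks()].
#' @param paths list of `projected_path` objects.
#' @param graph a [reaction_graph].
#' @param annotation the [read_annotation()] table (for the detected flag).
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the paths of the files written (`projected.graphml`,
#'   `edges.tsv`, `subnetworks.tsv`, `unprojectable.tsv`).
#' @export
export_network <- function(subnetworks, paths, graph, annotation, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  proj <- Filter(function(p) p$status == "projected", paths)
  nodes <- unique(unlist(lapply(proj, `[[`, "nodes")))
  g <- igraph::induced_subgraph(graph$graph, intersect(nodes, igraph::V(graph$graph)$name))
  detected_ids <- unique(unlist(annotation$node_ids[annotation$matched]))
  igraph::V(g)$detected <- igraph::V(g)$name %in% detected_ids
  gml <- file.path(out_dir, "projected.graphml")
  igraph::write_graph(g, gml, format = "graphml")
  ed <- igraph::as_data_frame(g, what = "edges")
  utils::write.table(ed, file.path(out_dir, "edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sn <- data.frame(pathway_id = vapply(subnetworks, `[[`, character(1), "pathway_id"),
                   pathway_name = vapply(subnetworks, function(s)
                     s$pathway_name %||% NA_character_, character(1)),
                   n_members = vapply(subnetworks, `[[`, integer(1), "n_members"))
  utils::write.table(sn, file.path(out_dir, "subnetworks.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  un <- Filter(function(p) p$status == "unprojectable", paths)
  ut <- data.frame(source = vapply(un, `[[`, character(1), "source"),
                   target = vapply(un, `[[`, character(1), "target"),
                   reason = vapply(un, `[[`, character(1), "reason"))
  utils::write.table(ut, file.path(out_dir, "unprojectable.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file.path(out_dir, c("projected.graphml", "edges.tsv",
                                 "subnetworks.tsv", "unprojectable.tsv")))
}
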