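# panel + annotation shared by the projection tests
proj_panel <- function() {
  flux_panel(seq(0, 55, 5), matrix(runif(60), 12, 5),
             mz = c(33.033, 31.018, 47.013, 60.081, 46.065))
}
proj_annotation <- function(graph = NULL) {
  f <- write_annotation_file(data.frame(
    mz = c(33.033, 31.018, 47.013, 60.081, 46.065),
    compound = c("methanol", "formaldehyde", "formate", "trimethylamine",
                 "dimethylamine"),
    node_ids = c("C00132", "C00067", "C00058", "C00565", "C00543")))
  suppressMessages(read_annotation(f, proj_panel(), graph = graph))
}

test_that("a single-reaction connection projects as metabolite-gene-metabolite", {
  g <- read_reaction_graph(toy_graph_file())
  ann <- proj_annotation(g)
  pp <- project_connection(list(source = "33.033", target = "31.018"), ann, g)
  expect_identical(pp$status, "projected")
  expect_identical(pp$nodes, c("C00132", "G_mdh", "C00067"))
  expect_equal(pp$length, 2L)
  expect_identical(pp$pathways, "P1")
})

test_that("the shorter of two alternative routes wins and matches enumeration", {
  # methanol -> formaldehyde has the direct 2-edge route; TMA -> formaldehyde
  # only the 4-edge route through DMA
  g <- read_reaction_graph(toy_graph_file())
  ann <- proj_annotation(g)
  pp <- project_connection(list(source = "60.081", target = "31.018"), ann, g)
  expect_equal(pp$length, 4L)
  e <- igraph::as_data_frame(g$graph, what = "edges")
  expect_equal(pp$length, oracle_shortest(e$from, e$to, "C00565", "C00067"))
  # reversed direction is unreachable in the directed graph
  back <- project_connection(list(source = "31.018", target = "60.081"), ann, g)
  expect_identical(back$status, "unprojectable")
  expect_match(back$reason, "no directed path")
})

test_that("unannotated endpoints are flagged, not dropped", {
  g <- read_reaction_graph(toy_graph_file())
  p <- proj_panel()
  ann <- suppressMessages(read_annotation(write_annotation_file(data.frame(
    mz = 33.033, compound = "methanol", node_ids = "C00132")), p, graph = g))
  pp <- project_connection(list(source = "47.013", target = "33.033"), ann, g)
  expect_identical(pp$status, "unprojectable")
  expect_match(pp$reason, "unannotated")
})

test_that("ambiguous annotations resolve to the globally shortest projection", {
  g <- read_reaction_graph(toy_graph_file())
  p <- proj_panel()
  # source channel could be TMA or methanol; methanol gives the 2-edge path
  ann <- suppressMessages(read_annotation(write_annotation_file(data.frame(
    mz = c(33.033, 31.018), compound = c("ambiguous", "formaldehyde"),
    node_ids = c("C00565,C00132", "C00067"))), p, graph = g))
  pp <- project_connection(list(source = "33.033", target = "31.018"), ann, g)
  expect_equal(pp$length, 2L)
  expect_identical(pp$nodes[1], "C00132")
})

test_that("projected path lengths equal the exhaustive-search minimum", {
  for (seed in 1:20) {
    g <- random_bipartite_graph(n_met = 12, n_gene = 12, n_edges = 40,
                                seed = seed)
    e <- igraph::as_data_frame(g$graph, what = "edges")
    mets <- igraph::V(g$graph)$name[igraph::V(g$graph)$kind == "metabolite"]
    ends <- sample(mets, 2)
    ann <- structure(data.frame(channel = c("33.033", "45.033"),
                                matched = TRUE),
                     class = c("channel_annotation", "data.frame"))
    ann$node_ids <- list(ends[1], ends[2])
    pp <- project_connection(list(source = "33.033", target = "45.033"), ann, g)
    want <- oracle_shortest(e$from, e$to, ends[1], ends[2])
    if (is.infinite(want)) expect_identical(pp$status, "unprojectable")
    else expect_equal(pp$length, want)
  }
})

test_that("adding an edge never lengthens a projected path", {
  set.seed(99)
  for (k in 1:8) {
    g <- random_bipartite_graph(12, 12, 40, seed = 100 + k)
    mets <- igraph::V(g$graph)$name[igraph::V(g$graph)$kind == "metabolite"]
    genes <- igraph::V(g$graph)$name[igraph::V(g$graph)$kind == "gene"]
    ends <- sample(mets, 2)
    ann <- structure(data.frame(channel = c("33.033", "45.033"), matched = TRUE),
                     class = c("channel_annotation", "data.frame"))
    ann$node_ids <- list(ends[1], ends[2])
    conn <- list(source = "33.033", target = "45.033")
    before <- project_connection(conn, ann, g)
    g2 <- g
    g2$graph <- igraph::add_edges(g$graph, c(ends[1], sample(genes, 1)),
                                  attr = list(reaction = "Rx", pathways = "P1"))
    after <- project_connection(conn, ann, g2)
    if (before$status == "projected") {
      expect_identical(after$status, "projected")
      expect_lte(after$length, before$length)
    }
  }
})

test_that("sub-networks require two member paths; shared membership counts in both", {
  g <- read_reaction_graph(toy_graph_file())
  mkpath <- function(nodes, pw) structure(
    list(source = "a", target = "b", status = "projected", nodes = nodes,
         length = length(nodes) - 1L, pathways = pw), class = "projected_path")
  paths <- list(mkpath(c("C00132", "G_mdh", "C00067"), "P1"),
                mkpath(c("C00067", "G_fdh", "C00058"), "P1"),
                mkpath(c("C00565", "G_tmm", "C00543"), c("P1", "P2")))
  sn <- extract_subnetworks(paths, g)
  expect_length(sn, 1L)                                # P2 has only one member
  expect_identical(sn[[1]]$pathway_id, "P1")
  expect_equal(sn[[1]]$n_members, 3L)                  # third path counts for P1 too
  sn2 <- extract_subnetworks(paths[c(1, 3)], g)
  expect_length(sn2, 1L)                               # P1 via members 1 and 3
  expect_length(extract_subnetworks(list(), g), 0L)
  expect_length(extract_subnetworks(paths[1], g), 0L)
})

test_that("exported GraphML round-trips and carries the detected flag", {
  g <- read_reaction_graph(toy_graph_file())
  ann <- proj_annotation(g)
  paths <- list(project_connection(list(source = "33.033", target = "31.018"),
                                   ann, g),
                project_connection(list(source = "31.018", target = "47.013"),
                                   ann, g))
  sn <- extract_subnetworks(paths, g)
  out <- export_network(sn, paths, g, ann, tempfile("proj"))
  expect_true(all(file.exists(out)))
  back <- igraph::read_graph(out[1], format = "graphml")
  expect_equal(igraph::vcount(back), 5)                # two 2-edge paths
  expect_equal(igraph::ecount(back), 4)
  expect_true(all(igraph::V(back)$detected[igraph::V(back)$kind == "metabolite"]))
  expect_false(any(igraph::V(back)$detected[igraph::V(back)$kind == "gene"]))
  sn_tab <- read.table(out[3], header = TRUE, sep = "\t")
  expect_equal(sn_tab$pathway_id, "P1")
})

test_that("triads project as forked paths to the shared target", {
  g <- read_reaction_graph(toy_graph_file())
  ann <- proj_annotation(g)
  net <- list(top = data.frame(source = "33.033", target = "31.018"),
              triads = data.frame(source1 = "33.033", source2 = "46.065",
                                  target = "31.018"))
  paths <- project_network(net, ann, g)
  expect_length(paths, 3L)                             # pair + two triad prongs
  origins <- vapply(paths, attr, character(1), "origin")
  expect_equal(sum(origins == "triad"), 2L)
  lens <- vapply(paths, `[[`, integer(1), "length")
  expect_equal(lens, c(2L, 2L, 2L))                    # DMA -> formaldehyde is 2 edges
})

test_that("an empty projection still exports valid documents", {
  g <- read_reaction_graph(toy_graph_file())
  out <- export_network(list(), list(), g, proj_annotation(g), tempfile("empty"))
  expect_true(all(file.exists(out)))
  back <- igraph::read_graph(out[1], format = "graphml")
  expect_equal(igraph::vcount(back), 0)
})
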