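stub_fetcher <- function(map) {
  function(mirna, disease) {
    key <- paste(mirna, disease, sep = "|")
    if (!is.null(map[[key]])) map[[key]] else character(0)
  }
}

test_that("evidence search records per-miRNA PubMed co-occurrence hits", {
  map <- list(
    "hsa-mir-506|breast cancer" = c("23717581", "25707493", "26059632",
                                    "26398880", "27542202"),
    "hsa-mir-520d-5p|breast cancer" = "28721278"
  )
  ev <- search_evidence(c("hsa-miR-506", "hsa-miR-520d-5p", "hsa-miR-999"),
                        "breast cancer", stub_fetcher(map))
  expect_equal(ev$n_hits, c(5L, 1L, 0L))
  expect_equal(ev$pubmed_ids[[1]],
               c("23717581", "25707493", "26059632", "26398880",
                 "27542202"))
  expect_equal(ev$pubmed_ids[[3]], character(0))
  expect_false(attr(ev, "partial"))
  expect_identical(search_evidence("hsa-miR-506", "breast cancer",
                                   stub_fetcher(map))$n_hits, 5L)
})

test_that("a failing fetcher marks only its own row and flags the table", {
  flaky <- function(mirna, disease) {
    if (mirna == "m2") stop("connection reset") else "11111111"
  }
  ev <- search_evidence(c("m1", "m2", "m3"), "breast cancer", flaky)
  expect_equal(ev$status, c("ok", "connection reset", "ok"))
  expect_equal(ev$n_hits, c(1L, 0L, 1L))
  expect_true(attr(ev, "partial"))
  expect_error(search_evidence("m1", "", flaky), "disease_name")
})

test_that("result graph contains the expected node and edge classes", {
  net <- toy_network()
  assoc <- make_assoc("D1", "toy disease", "m1")
  ranking <- suppressMessages(rank_mirnas(net, assoc, "D1"))
  g <- build_result_graph(ranking, net, assoc, "D1", top = 2)

  cls <- igraph::V(g)$node_class
  expect_equal(sum(cls == "disease"), 1L)
  expect_equal(sum(cls == "known_mirna"), 1L)
  expect_equal(sum(cls == "candidate_mirna"), 2L)
  expect_equal(sum(cls == "pubmed"), 0L)
  # genes of m1 (known) + m2, m3 (candidates): g1..g4
  expect_setequal(igraph::V(g)$name[cls == "gene"],
                  c("g1", "g2", "g3", "g4"))
  expect_setequal(unique(igraph::E(g)$edge_class),
                  c("known_association", "candidate_association", "targets"))
  ranks <- igraph::V(g)$rank[cls == "candidate_mirna"]
  expect_setequal(ranks, c(1, 2))

  ev <- search_evidence("m2", "toy disease",
                        stub_fetcher(list("m2|toy disease" =
                                            as.character(1:5))))
  g2 <- build_result_graph(ranking, net, assoc, "D1", evidence = ev)
  expect_equal(sum(igraph::V(g2)$node_class == "pubmed"), 5L)
  expect_equal(sum(igraph::E(g2)$edge_class == "evidence"), 5L)
})

test_that("GraphML export round-trips and SIF line count equals edge count", {
  net <- toy_network()
  assoc <- make_assoc("D1", "toy disease", "m1")
  ranking <- suppressMessages(rank_mirnas(net, assoc, "D1"))
  out <- file.path(withr::local_tempdir(), "graph")

  files <- export_result_graph(ranking, net, assoc, "D1",
                               format = "graphml", out = out)
  g <- build_result_graph(ranking, net, assoc, "D1")
  g2 <- igraph::read_graph(files[[1]], format = "graphml")
  expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
  expect_equal(sort(igraph::V(g2)$node_class), sort(igraph::V(g)$node_class))
  expect_equal(sort(igraph::E(g2)$edge_class), sort(igraph::E(g)$edge_class))
  expect_equal(igraph::ecount(g2), igraph::ecount(g))

  sif_files <- export_result_graph(ranking, net, assoc, "D1",
                                   format = "sif", out = out)
  expect_equal(length(readLines(sif_files[[1]])), igraph::ecount(g))
  nodes <- read.delim(sif_files[[2]])
  expect_equal(nrow(nodes), igraph::vcount(g))
})

test_that("service facade mirrors the list/filter/rank/get operations", {
  sim <- generate_synthetic(rng_seed = 1)
  paths <- synthetic_files(sim)
  svc <- suppressMessages(mirna_rank_service(paths$network,
                                             paths$associations))

  all_d <- svc$disease_list()
  expect_equal(all_d$disease_id, "SYN1")
  expect_equal(svc$disease_list("SYNTHETIC MODULE")$disease_id, "SYN1")
  expect_equal(nrow(svc$disease_list("no such disease")), 0L)

  expect_error(svc$get_rank(5), "409")
  expect_error(suppressMessages(svc$rank("NOPE")), "unknown disease")

  suppressMessages(svc$rank("SYN1"))
  top10 <- svc$get_rank(10)
  expect_equal(nrow(top10), 10L)
  expect_true(all(diff(top10$score) <= 0))
  expect_equal(nrow(svc$get_rank(0)), 0L)
  expect_equal(nrow(svc$get_rank(10^6)), 60L - 8L)

  js <- jsonlite::fromJSON(svc$get_rank(3, as_json = TRUE))
  expect_equal(js$mirna, top10$mirna[1:3])
})

test_that("CLI rank runs end-to-end and respects --top and --candidates", {
  sim <- generate_synthetic(rng_seed = 1)
  dir <- withr::local_tempdir()
  paths <- synthetic_files(sim, dir)
  out <- file.path(dir, "ranking.tsv")

  status <- suppressMessages(cli_main(c(
    "rank", "--network", paths$network, "--associations",
    paths$associations, "--disease", "SYN1", "--out", out)))
  expect_equal(status, 0L)
  tab <- read.delim(out, comment.char = "#")
  expect_equal(nrow(tab), 60L - 8L)        # all miRNAs minus the 8 seeds
  expect_true(all(diff(tab$score) <= 0))

  out_top <- file.path(dir, "top.tsv")
  suppressMessages(cli_main(c(
    "rank", "--network", paths$network, "--associations",
    paths$associations, "--disease", "SYN1", "--top", "10",
    "--out", out_top)))
  expect_lte(nrow(read.delim(out_top, comment.char = "#")), 10L)

  cand_file <- file.path(dir, "candidates.txt")
  seed_mirna <- sim$truth$known_mirnas[[1]]
  writeLines(c("mir020", "mir021", seed_mirna, "not-a-mirna"), cand_file)
  out_cand <- file.path(dir, "cand.tsv")
  # the candidate that is also a seed is dropped with a warning
  expect_warning(
    suppressMessages(cli_main(c(
      "rank", "--network", paths$network, "--associations",
      paths$associations, "--disease", "SYN1", "--candidates", cand_file,
      "--out", out_cand))),
    "seed miRNAs")
  got <- read.delim(out_cand, comment.char = "#")
  expect_true(all(got$mirna %in% setdiff(c("mir020", "mir021"),
                                         sim$truth$known_mirnas)))
  expect_false(seed_mirna %in% got$mirna)

  bad <- suppressMessages(cli_main(c(
    "rank", "--network", paths$network, "--associations",
    paths$associations, "--disease", "NOPE", "--out", out)))
  expect_equal(bad, 1L)
})

test_that("CLI and service facade produce identical ranking rows", {
  sim <- generate_synthetic(rng_seed = 4)
  dir <- withr::local_tempdir()
  paths <- synthetic_files(sim, dir)
  out <- file.path(dir, "cli.tsv")
  suppressMessages(cli_main(c(
    "rank", "--network", paths$network, "--associations",
    paths$associations, "--disease", "SYN1", "--out", out)))
  cli_rows <- read.delim(out, comment.char = "#")

  svc <- suppressMessages(mirna_rank_service(paths$network,
                                             paths$associations))
  suppressMessages(svc$rank("SYN1"))
  svc_rows <- svc$get_rank(nrow(cli_rows))
  expect_equal(cli_rows$mirna, svc_rows$mirna)
  expect_equal(cli_rows$score, svc_rows$score, tolerance = 1e-15)
})

test_that("CLI simulate, loocv, sweep and diseases subcommands work", {
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "sim")
  expect_equal(suppressMessages(cli_main(c("simulate", "--seed", "1",
                                           "--out", prefix))), 0L)
  net_path <- paste0(prefix, ".network.tsv")
  assoc_path <- paste0(prefix, ".associations.tsv")
  expect_true(file.exists(net_path) && file.exists(assoc_path))

  loocv_out <- file.path(dir, "loocv.tsv")
  expect_equal(suppressMessages(cli_main(c(
    "loocv", "--network", net_path, "--associations", assoc_path,
    "--disease", "SYN1", "--out", loocv_out))), 0L)
  expect_true(any(grepl("^# AUC:", readLines(loocv_out))))

  sweep_out <- file.path(dir, "sweep.tsv")
  # small grid via standalone function; the CLI default grid is exercised
  # in the acceptance suite
  dis_out <- file.path(dir, "diseases.tsv")
  expect_equal(suppressMessages(cli_main(c(
    "diseases", "--associations", assoc_path, "--query", "synthetic",
    "--out", dis_out))), 0L)
  expect_equal(read.delim(dis_out)$disease_id, "SYN1")
})
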