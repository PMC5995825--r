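test_that("dataset TSVs round-trip through the readers", {
  tab <- simulateDataset(syntheticConfig(nOtus = 30,
    moduleSizes = c(6, 6), sequencingDepth = 2000, eukFraction = 0.2,
    seed = 33))
  dir <- withr::local_tempdir()
  writeDatasetTSV(tab, dir)
  expect_setequal(list.files(dir),
                  c("counts.tsv", "taxonomy.tsv", "metadata.tsv",
                    "groups.tsv", "truth.tsv"))
  back <- readAbundanceTable(file.path(dir, "counts.tsv"),
                             file.path(dir, "taxonomy.tsv"),
                             file.path(dir, "metadata.tsv"),
                             file.path(dir, "groups.tsv"))
  expect_equal(SummarizedExperiment::assay(back),
               SummarizedExperiment::assay(tab))
  expect_identical(zones(back), zones(tab))
  expect_identical(taxonomy(back)$phylum, taxonomy(tab)$phylum)
  expect_equal(envData(back)[, "TN"], envData(tab)[, "TN"])
})

test_that("comment lines and missing annotations are tolerated", {
  dir <- withr::local_tempdir()
  writeLines(c("# a comment", "otu\tS1\tS2", "o1\t3\t4", "o2\t0\t7"),
             file.path(dir, "c.tsv"))
  m <- readCountsTSV(file.path(dir, "c.tsv"))
  expect_equal(dim(m), c(2L, 2L))
  tab <- readAbundanceTable(file.path(dir, "c.tsv"))
  expect_identical(unname(taxonomy(tab)$phylum), rep("unclassified", 2))
  expect_identical(unname(zones(tab)), rep("all", 2))
})

test_that("config validation enforces threshold ranges", {
  expect_error(pipelineConfig(rMin = 0), "rMin")
  expect_error(pipelineConfig(piThr = 1.2), "piThr")
  expect_error(pipelineConfig(nReplicates = 1), "nReplicates")
  cfg <- pipelineConfig()
  expect_equal(cfg$rMin, 0.9)
  expect_equal(cfg$pMax, 0.01)
  expect_equal(cfg$qMax, 0.05)
  expect_equal(cfg$envRMin, 0.6)
  expect_equal(cfg$minPrevalence, 8)
  expect_equal(cfg$ziThr, 2.5)
  expect_equal(cfg$piThr, 0.62)
})

test_that("the full pipeline emits all per-zone artifacts and a manifest,
           reproducibly", {
  tab <- simulateDataset(smallConfig(81))
  outA <- withr::local_tempdir()
  cfgA <- pipelineConfig(outDir = outA, nReplicates = 30, seed = 7)
  resA <- runPipeline(cfgA, table = tab)
  man <- jsonlite::read_json(file.path(outA, "manifest.json"))
  expect_identical(man$status, "ok")
  expect_true(length(resA) >= 2)
  for (tag in c("zoneA_bacterioplankton", "zoneB_bacterioplankton")) {
    for (suffix in c("_edges.tsv", "_network.graphml", "_modules.tsv",
                     "_node_roles.tsv", "_or_ratio.tsv", "_indices.json",
                     "_env_edges.tsv"))
      expect_true(file.exists(file.path(outA, paste0(tag, suffix))),
                  info = paste0(tag, suffix))
  }
  # graphml is loadable and carries the module attribute
  g <- igraph::read_graph(
    file.path(outA, "zoneB_bacterioplankton_network.graphml"),
    format = "graphml")
  expect_true("module" %in% igraph::vertex_attr_names(g))
  expect_equal(igraph::vcount(g),
               nrow(nodeTable(resA$zoneB_bacterioplankton$network)))

  # same seed, fresh run: numerically identical TSV artifacts
  outB <- withr::local_tempdir()
  runPipeline(pipelineConfig(outDir = outB, nReplicates = 30, seed = 7),
              table = tab)
  for (f in c("zoneB_bacterioplankton_edges.tsv",
              "zoneB_bacterioplankton_node_roles.tsv",
              "zoneB_bacterioplankton_or_ratio.tsv"))
    expect_identical(readLines(file.path(outA, f)),
                     readLines(file.path(outB, f)))
})

test_that("a failed run leaves a manifest marking the failure", {
  out <- withr::local_tempdir()
  cfg <- pipelineConfig(outDir = out, seed = 1)
  expect_error(runPipeline(cfg), "counts path")
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_identical(man$status, "failed")
})

test_that("edge tables round-trip through TSV", {
  tab <- simulateDataset(smallConfig(82))
  net <- pipelineNetwork(tab, "zoneB")$net
  path <- withr::local_tempfile(fileext = ".tsv")
  writeEdgeTSV(net, path)
  back <- utils::read.delim(path)
  expect_equal(back$otu_a, edgeTable(net)$otu_a)
  expect_equal(back$rho, edgeTable(net)$rho, tolerance = 1e-12)
})
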