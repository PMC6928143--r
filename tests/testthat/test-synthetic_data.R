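test_that("the generated bundle is byte-identical across runs", {
  cfg <- synthetic_config(seed = 7, n_universe = 400, n_pathways = 40,
                          dataset_sizes = list(`1` = c(20, 20), `2` = c(5, 5),
                                               `3` = 30, `4` = 12,
                                               `5` = c(20, 10), `6` = c(10, 10),
                                               `7` = 60, `8` = 8, `9` = 10),
                          planted_hubs = data.frame(
                            identifier = sprintf("G%04d", 101:102),
                            serials = c("1,3,5", "3,5,6")),
                          planted_pathways = data.frame(
                            pathway = "PW001", serials = "1,5",
                            overlap_frac = 0.5))
  d1 <- file.path(tempdir(), "syn_a"); d2 <- file.path(tempdir(), "syn_b")
  generate_bundle(cfg, d1)
  generate_bundle(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE),
                     info = f)
  }
})

test_that("default dataset sizes mirror the study layout", {
  cfg <- synthetic_config(seed = 1)
  gen <- generate_kb(cfg)
  datasets <- generate_datasets(cfg, gen$kb)
  sizes <- vapply(datasets, function(d) nrow(d$records), integer(1))
  expect_equal(unname(sizes), c(280, 50, 218, 12, 346, 57, 1469, 8, 28))
  fc1 <- datasets[["1"]]$records$fold_change
  expect_equal(sum(fc1 >= 1), 114)
  expect_equal(sum(fc1 <= -1), 166)
  fc5 <- datasets[["5"]]$records$fold_change
  expect_equal(sum(fc5 >= 1), 233)
  expect_equal(sum(fc5 <= -1), 113)
  expect_true(all(abs(c(fc1, fc5)) >= 1.5 - 1e-9))
  expect_true(all(abs(c(fc1, fc5)) <= 10 + 1e-9))
  # mapping serials are presence-only
  expect_true(all(is.na(datasets[["7"]]$records$fold_change)))
})

test_that("planted hubs satisfy their construction guarantee in the graph", {
  cfg <- synthetic_config(seed = 3)
  gen <- generate_kb(cfg)
  deg <- igraph::degree(gen$kb$graph$igraph)
  names(deg) <- igraph::V(gen$kb$graph$igraph)$name
  expect_true(all(deg[cfg$planted_hubs$identifier] >= 5))
  # planted material appears in its assigned datasets
  datasets <- generate_datasets(cfg, gen$kb)
  hub_serials <- strsplit(cfg$planted_hubs$serials, ",")
  for (i in seq_len(nrow(cfg$planted_hubs))) {
    for (s in hub_serials[[i]]) {
      expect_true(cfg$planted_hubs$identifier[i] %in%
                    datasets[[s]]$records$identifier)
    }
  }
  pw_serials <- strsplit(cfg$planted_pathways$serials, ",")
  for (j in seq_len(nrow(cfg$planted_pathways))) {
    pw <- gen$kb$pathways[[cfg$planted_pathways$pathway[j]]]
    need <- ceiling(cfg$planted_pathways$overlap_frac[j] * length(pw$members))
    for (s in pw_serials[[j]]) {
      got <- length(intersect(pw$members, datasets[[s]]$records$identifier))
      expect_gte(got, need)
    }
  }
})

test_that("the emitted SIF has no duplicate or reversed-duplicate edges", {
  cfg <- synthetic_config(seed = 2, n_universe = 300, n_pathways = 20,
                          planted_pathway_size = 16,
                          dataset_sizes = list(`1` = c(15, 15), `2` = c(5, 5),
                                               `3` = 30, `4` = 12,
                                               `5` = c(15, 15), `6` = c(5, 5),
                                               `7` = 30, `8` = 8, `9` = 10),
                          planted_hubs = data.frame(
                            identifier = "G0101", serials = "1,3,5"),
                          planted_pathways = data.frame(
                            pathway = "PW001", serials = "1,5",
                            overlap_frac = 0.5))
  dir <- file.path(tempdir(), "syn_sif")
  b <- generate_bundle(cfg, dir)
  lines <- readLines(b$paths$sif)
  parts <- strsplit(lines, "\t")
  key <- vapply(parts, function(p) paste(sort(p[c(1, 3)]), collapse = "|"),
                character(1))
  expect_false(any(duplicated(key)))
  expect_equal(length(lines), igraph::ecount(b$kb$graph$igraph))
  # round-trip: reloading reproduces the same graph
  g2 <- load_interactions(b$paths$sif)
  expect_equal(igraph::ecount(g2$igraph), igraph::ecount(b$kb$graph$igraph))
})

test_that("noiseless PTM generation recovers planted ratios exactly", {
  cfg <- synthetic_config(seed = 5, noise_sigma = 0)
  tab <- generate_ptm_table(cfg)
  out <- quantify_table(tab)
  expect_equal(nrow(out$measurements), nrow(cfg$ptm_planted))
  got <- stats::setNames(out$measurements$signed_ratio, out$measurements$gene)
  want <- stats::setNames(cfg$ptm_planted$signed_ratio, cfg$ptm_planted$gene)
  expect_equal(got[names(want)], want, tolerance = 1e-12)
})

test_that("noisy PTM ratios stay near the planted truth", {
  planted <- data.frame(
    gene = sprintf("G%04d", 1001:1200),
    peptide = "SAMPLEK",
    sites = "S1",
    signed_ratio = rep(c(2.5, -2.5, 4, -1.5), 50))
  cfg <- synthetic_config(seed = 9, noise_sigma = 0.1, ptm_planted = planted)
  tab <- generate_ptm_table(cfg)
  out <- quantify_table(tab)
  log_err <- abs(log(abs(out$measurements$signed_ratio)) -
                   log(abs(planted$signed_ratio[match(out$measurements$gene,
                                                      planted$gene)])))
  # each group total carries ~ sigma/sqrt(2) log-noise, their difference
  # ~ sigma; median |N(0, sigma)| = 0.674 sigma, doubled as a slack bound
  expect_lt(stats::median(log_err), 2 * 0.674 * 0.1)
})
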