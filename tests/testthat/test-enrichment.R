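test_that("hypergeom_tail matches exhaustive enumeration on small universes", {
  expect_equal(hypergeom_tail(0, 3, 4, 10), 1)
  expect_equal(hypergeom_tail(5, 5, 5, 10), 1 / 252)
  expect_equal(hypergeom_tail(1, 2, 2, 4), 5 / 6)

  for (N in c(6, 9, 12)) {
    for (K in c(2, N %/% 2)) {
      for (n in c(3, N %/% 2)) {
        for (k in 0:min(K, n)) {
          expect_equal(hypergeom_tail(k, K, n, N),
                       enum_hyper_tail(k, K, n, N),
                       tolerance = 1e-12,
                       info = sprintf("k=%d K=%d n=%d N=%d", k, K, n, N))
        }
      }
    }
  }
})

test_that("hypergeom_tail is non-increasing in k and validates its domain", {
  tails <- vapply(0:5, hypergeom_tail, numeric(1), K = 5, n = 6, N = 14)
  expect_true(all(diff(tails) <= 1e-14))
  expect_error(hypergeom_tail(6, 5, 6, 14), "min")
  expect_error(hypergeom_tail(2, 15, 6, 14), "exceed N")
  expect_error(hypergeom_tail(-1, 5, 6, 14), "non-negative")
})

test_that("bh_adjust reproduces hand-computed step-up adjustments", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  expect_error(bh_adjust(c(0.2, 1.2)), "\\[0, 1\\]")

  set.seed(11)
  for (rep in 1:20) {
    p <- stats::runif(sample(1:30, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, hand_bh(p))
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    # monotone in the sorted order
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})

test_that("enrich_dataset ranks a fully recovered pathway first", {
  kb <- toy_kb()
  res <- enrich_dataset(kb$pathways$PWA$members, kb)
  expect_equal(res$pathway[1], "PWA")
  expect_equal(res$k[1], 4)
  expect_equal(res$n[1], 4)
  expect_equal(res$N[1], 12)
  expect_equal(res$p_value[1], enum_hyper_tail(4, 4, 4, 12), tolerance = 1e-12)
  expect_true(all(res$adjusted_p >= res$p_value))
  expect_equal(res$significant, res$adjusted_p < 0.05)
  expect_equal(res$overlap[1], paste(sort(kb$pathways$PWA$members),
                                     collapse = ";"))
})

test_that("enrich_dataset handles empty queries and out-of-universe identifiers", {
  kb <- toy_kb()
  expect_equal(nrow(enrich_dataset(character(0), kb)), 0)
  expect_warning(res <- enrich_dataset(c("T01", "OUTSIDER"), kb), "dropped")
  expect_equal(res$n[1], 1)
})

test_that("a strongly planted overlap is significant after BH", {
  # 30 of a 40-member pathway inside a 280-molecule query, universe 2000
  universe <- sprintf("U%04d", 1:2000)
  pws <- list(BIG = list(name = "BIG", members = universe[1:40],
                         cancer_related = FALSE, panel_label = NA_character_))
  for (j in 2:50) {
    pws[[sprintf("R%02d", j)]] <- list(name = sprintf("R%02d", j),
                                       members = universe[40 + (j * 30):(j * 30 + 29)],
                                       cancer_related = FALSE,
                                       panel_label = NA_character_)
  }
  g <- interaction_graph(data.frame(from = universe[1], to = universe[2],
                                    relation = "direct"))
  kb <- knowledge_base(g, pws, universe = universe)
  eligible <- c(universe[1:30], universe[1700:1949])
  res <- enrich_dataset(eligible, kb)
  expect_true(res$significant[res$pathway == "BIG"])
})

test_that("p-values are superuniform under the null", {
  set.seed(99)
  universe <- sprintf("U%03d", 1:400)
  pws <- list(P = list(name = "P", members = universe[1:40],
                       cancer_related = FALSE, panel_label = NA_character_))
  g <- interaction_graph(data.frame(from = universe[1], to = universe[2],
                                    relation = "direct"))
  kb <- knowledge_base(g, pws, universe = universe)
  p <- replicate(400, {
    enrich_dataset(sample(universe, 50), kb)$p_value[1]
  })
  for (t in c(0.05, 0.1, 0.25, 0.5)) {
    expect_lt(mean(p <= t), t + 0.07)
  }
})

test_that("shared_pathways intersects significance across datasets", {
  mk <- function(sig) data.frame(pathway = names(sig), significant = sig,
                                 stringsAsFactors = FALSE)
  per <- list(
    `1` = mk(c(PWA = TRUE, PWB = TRUE, PWC = FALSE)),
    `5` = mk(c(PWA = TRUE, PWB = FALSE, PWC = FALSE)),
    `7` = mk(c(PWA = FALSE, PWB = FALSE, PWC = TRUE))
  )
  labels <- data.frame(pathway = c("PWA", "PWB", "PWC"),
                       cancer_related = c(TRUE, FALSE, FALSE),
                       panel_label = c("panel_a", NA, NA))
  out <- shared_pathways(per, min_datasets = 2, labels = labels)
  expect_equal(out$pathway, "PWA")
  expect_equal(out$dataset_serials, "1,5")
  expect_equal(out$n_datasets, 2)
  expect_true(out$cancer_related)
  expect_equal(out$panel_label, "panel_a")

  # brute-force comparison at min_datasets = 1
  all_out <- shared_pathways(per, min_datasets = 1, labels = labels)
  brute <- sapply(c("PWA", "PWB", "PWC"), function(pw) {
    sum(vapply(per, function(d) d$significant[d$pathway == pw], logical(1)))
  })
  expect_equal(stats::setNames(all_out$n_datasets, all_out$pathway),
               sort(brute[brute >= 1], decreasing = TRUE))
  expect_error(shared_pathways(per, min_datasets = 0), ">= 1")
})
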