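small_cfg <- function(...) {
  run_config(L = 8, K = 5, n_landscapes = 40, master_seed = 31, ...)
}

test_that("step frequency tables are well-formed", {
  ens <- simulate_walk_ensemble(small_cfg())
  sf <- epistasis_by_step(ens)
  expect_true(all(abs(sf$freq_sign + sf$freq_synergistic +
                        sf$freq_antagonistic + sf$freq_none - 1) < 1e-12))
  expect_true(all(diff(sf$n_walks) <= 0))  # walks stop at local optima
  expect_equal(sf$n + sf$n_degenerate, sf$n_walks)
})

test_that("short walks and K = 0 landscapes give the degenerate tables", {
  # all walks too short for a window: empty table
  lnd <- rmf_landscape(L = 4, slope = 1, noise = c(0.4, 0.4), seed = 32)
  wk <- run_walk(lnd, c(1L, 1L, 1L, 0L), seed = 33)  # one step to the peak
  expect_equal(nrow(epiwalk:::walk_records(wk, lnd)), 0L)

  # K = 0: every record classifies as none on the multiplicative scale
  # (uniform starts: a realized small multiplicative landscape need not have
  # any genotype below the ensemble-level low-fitness threshold)
  ens0 <- simulate_walk_ensemble(run_config(L = 8, K = 0, n_landscapes = 25,
                                            start_rule = "uniform",
                                            master_seed = 34))
  sf0 <- epistasis_by_step(ens0)
  expect_gt(sum(sf0$n), 0)
  expect_true(all(sf0$freq_none == 1))
})

test_that("quartile tables mirror the walk-step trends", {
  qf <- ant_syn_ratio(epistasis_by_quartile(small_cfg(), n_per_stratum = 400))
  expect_equal(qf$quartile, 1:4)
  expect_equal(qf$n + qf$n_degenerate, rep(400L, 4))
  expect_gt(qf$freq_sign[4], qf$freq_sign[1])
  expect_gt(qf$ant_syn_ratio[1], qf$ant_syn_ratio[4])
})

test_that("percentile intervals are ordered and windows behave", {
  ens <- simulate_walk_ensemble(small_cfg())
  for (w in c("early", "late")) {
    iv <- mean_regression_intervals(ens, w)
    expect_true(all(iv$`p2.5` <= iv$median & iv$median <= iv$`p97.5`))
    expect_setequal(as.character(iv$role), c("ab", "Ab", "AB", "aB", "control"))
  }
  # no walk reaches the late window -> explicit signal
  short <- simulate_walk_ensemble(run_config(L = 4, K = 2, n_landscapes = 3,
                                             start_rule = "uniform",
                                             master_seed = 35))
  expect_error(mean_regression_intervals(short, "late"), "insufficient data")
})

test_that("arrow summaries count fitness-graph arrows", {
  lnd <- nk_landscape(L = 6, K = 3, seed = 36)
  W <- fitness_table(lnd)
  G <- epiwalk:::all_genotypes(6)
  peak <- arrow_summary(lnd, G[which.max(W), ])
  expect_equal(peak$n_out, 0L)
  expect_equal(peak$n_in, 6L)
  valley <- arrow_summary(lnd, G[which.min(W), ])
  expect_equal(valley$n_in, 0L)
  expect_equal(valley$n_out, 6L)
})

test_that("evolved genotypes sit on ridges (more in-arrows than random)", {
  set.seed(37)
  frac_in <- c()
  for (i in 1:30) {
    lnd <- nk_landscape(L = 10, K = 7, seed = 3700 + i)
    wk <- withr::with_seed(3800 + i,
                           run_walk(lnd, sample_low_fitness_genotype(lnd)))
    G <- attr(wk, "genotype_matrix")
    if (nrow(G) >= 4) {
      late <- G[nrow(G) - 1, ]  # just before the optimum
      frac_in <- c(frac_in, arrow_summary(lnd, late)$n_in / 10)
    }
  }
  expect_gt(mean(frac_in), 0.5)
})

test_that("local subgraph export spans the affected sub-hypercube", {
  skip_if_not_installed("igraph")
  lnd <- nk_landscape(L = 12, K = 8, seed = 38)
  wk <- NULL
  for (s in 1:50) {
    cand <- withr::with_seed(3900 + s,
                             run_walk(lnd, sample_low_fitness_genotype(lnd)))
    if (nrow(cand) >= 6) { wk <- cand; break }
  }
  expect_false(is.null(wk))
  g <- export_local_subgraph(lnd, wk, from_step = 1, n_steps = 5)
  expect_equal(igraph::vcount(g), 32)
  expect_equal(igraph::ecount(g), 80)  # 5 * 2^4
  # every walk edge is a graph edge oriented along the walk
  expect_equal(sum(igraph::E(g)$walk), 5L)
  # vertex fitness annotations match the landscape exactly
  full <- igraph::V(g)$full
  w <- fitness_many(lnd, do.call(rbind, lapply(full, gt_parse)))
  expect_equal(igraph::V(g)$fitness, w)
  # DOT export writes a parseable file
  f <- tempfile(fileext = ".dot")
  export_local_subgraph(lnd, wk, 1, 5, file = f)
  expect_true(file.exists(f))
  expect_true(any(grepl("digraph", readLines(f))))
  expect_error(export_local_subgraph(lnd, wk, nrow(wk) - 2, 5), "does not cover")
})
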