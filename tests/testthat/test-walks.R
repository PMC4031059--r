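test_that("fitter_neighbors returns strict improvements with s = w'/w - 1", {
  lnd <- rmf_landscape(L = 4, slope = 0.5, noise = c(0.2, 0.2), seed = 1)
  # all-derived genotype is the unique optimum: no fitter neighbor
  expect_equal(nrow(fitter_neighbors(lnd, rep(1L, 4))), 0L)

  # engineered single fitter neighbor with known ratio
  lnd2 <- nk_landscape(L = 2, K = 1, seed = 2)
  # table index for locus i is 1 + g[i] + 2 * g[neighbor]
  lnd2$contributions <- list(c(1.0, 1.2, 1.0, 1.2), c(1.0, 1.44, 1.0, 1.44))
  # g = (0,0): neighbor (1,0) has w = sqrt(1.2 * 1) and (0,1) w = sqrt(1 * 1.44)
  fn <- fitter_neighbors(lnd2, c(0L, 0L))
  expect_equal(fn$locus, c(1L, 2L))
  expect_equal(fn$s, c(sqrt(1.2) - 1, 0.2), tolerance = 1e-12)

  # exact ties are not beneficial
  lnd3 <- lnd2
  lnd3$contributions <- list(c(1, 1, 1, 1), c(1, 1, 1, 1))
  expect_equal(nrow(fitter_neighbors(lnd3, c(0L, 0L))), 0L)
})

test_that("fixation probabilities are proportional to selection coefficients", {
  expect_equal(fixation_probabilities(c(0.1, 0.3)), c(0.25, 0.75))
  expect_equal(fixation_probabilities(0.2), 1)
  expect_equal(fixation_probabilities(rep(0.07, 4)), rep(0.25, 4))
  expect_error(fixation_probabilities(numeric(0)), "local optimum")
  expect_error(fixation_probabilities(c(0.1, -0.1)), "positive")
})

test_that("walks satisfy all path invariants", {
  for (s in 1:6) {
    lnd <- nk_landscape(L = 8, K = 5, seed = s)
    wk <- run_walk(lnd, sample(c(0L, 1L), 8, replace = TRUE), seed = 100 + s)
    G <- attr(wk, "genotype_matrix")
    expect_true(all(diff(wk$fitness) > 0))
    if (nrow(G) > 1) {
      steps <- sapply(seq_len(nrow(G) - 1), function(t) which(G[t, ] != G[t + 1, ]))
      expect_true(all(lengths(as.list(steps)) == 1))   # Hamming-1 moves
      expect_true(all(diff(steps) != 0))               # never the same locus twice in a row
      expect_true(length(unique(steps)) == length(steps))  # strictly increasing fitness forbids revisits
    }
    expect_true(is_local_optimum(lnd, G[nrow(G), ]))
    expect_lte(nrow(G), 2^8)
  }
})

test_that("K = 0 walks climb straight to the global optimum under both schemes", {
  lnd <- nk_landscape(L = 7, K = 0, seed = 7)
  W <- fitness_table(lnd)
  opt <- epiwalk:::all_genotypes(7)[which.max(W), ]
  start <- 1L - opt  # antipode: Hamming distance 7
  for (scheme in c("sswm", "equal")) {
    wk <- run_walk(lnd, start, scheme = scheme, seed = 11)
    expect_equal(nrow(wk), 7 + 1)
    expect_equal(attr(wk, "genotype_matrix")[nrow(wk), ], opt)
  }
  # start at the optimum: a single-genotype walk
  expect_equal(nrow(run_walk(lnd, opt, seed = 12)), 1L)
})

test_that("equal-weight steps are uniform among fitter neighbors", {
  lnd <- nk_landscape(L = 6, K = 5, seed = 13)
  g0 <- epiwalk:::all_genotypes(6)[which.min(fitness_table(lnd)), ]
  k <- nrow(fitter_neighbors(lnd, g0))
  expect_gte(k, 3)
  set.seed(14)
  first <- replicate(600, run_walk(lnd, g0, scheme = "equal")$genotype[2])
  tab <- table(first)
  expect_equal(length(tab), k)
  expect_gt(chisq.test(tab)$p.value, 0.01)
})

test_that("SSWM gains fitness faster per early step than equal weighting", {
  gain <- function(scheme) {
    g <- numeric(0)
    for (i in 1:60) {
      lnd <- nk_landscape(L = 10, K = 7, seed = 700 + i)
      wk <- withr::with_seed(800 + i, {
        run_walk(lnd, sample_low_fitness_genotype(lnd), scheme = scheme)
      })
      if (nrow(wk) >= 2) g <- c(g, wk$fitness[2] - wk$fitness[1])
    }
    g
  }
  g_sswm <- gain("sswm")
  g_equal <- gain("equal")
  tt <- t.test(g_sswm, g_equal, alternative = "greater")
  expect_gt(mean(g_sswm), mean(g_equal))
  expect_lt(tt$p.value, 0.05)
})
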