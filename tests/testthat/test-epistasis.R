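make_quad <- function(w_ab, w_Ab, w_AB, w_aB) {
  # quadruple object with prescribed fitnesses on a 2-locus table landscape
  lnd <- rmf_landscape(L = 2, slope = 0.1, noise = c(0, 1), seed = 1)
  lnd$table <- c(w_ab, w_aB, w_Ab, w_AB)  # index order: 00, 01, 10, 11
  quadruple(c(0L, 0L), c(1L, 0L), c(1L, 1L), lnd)
}

test_that("walks yield one quadruple per two-step window", {
  lnd <- nk_landscape(L = 8, K = 6, seed = 21)
  set.seed(22)
  wk <- NULL
  while (is.null(wk) || nrow(wk) < 4) {
    wk <- run_walk(lnd, sample_low_fitness_genotype(lnd))
  }
  n <- nrow(wk)
  recs <- epiwalk:::walk_records(wk, lnd)
  expect_equal(nrow(recs), n - 2)
  expect_error(quadruple_from_walk(wk, n - 1, lnd), "no quadruple window")

  q <- quadruple_from_walk(wk, 1, lnd)
  G <- attr(wk, "genotype_matrix")
  expect_equal(q$genotypes["aB", ], complement_genotype(G[1, ], G[2, ], G[3, ]))
  # focal loci are the two flipped during the window
  flips <- c(which(G[1, ] != G[2, ]), which(G[2, ] != G[3, ]))
  expect_equal(q$focal, sort(flips))
  # walk convention guaranteed
  expect_true(q$w[["ab"]] < q$w[["Ab"]] && q$w[["Ab"]] < q$w[["AB"]])
})

test_that("epsilon matches hand-computed values on both scales", {
  q0 <- make_quad(1, 2, 4, 2)
  expect_equal(epsilon(q0, "multiplicative"), 0)
  q1 <- make_quad(1, 2, 5, 3)
  expect_equal(epsilon(q1, "additive"), 1)
  expect_equal(epsilon(q1, "multiplicative"), log(5 / 6))
})

test_that("classification follows the rank-of-aB rule", {
  expect_equal(as.character(classify_quadruple(make_quad(1, 1.2, 1.5, 1.6))$label), "sign")   # rank 1
  expect_equal(classify_quadruple(make_quad(1, 1.2, 1.5, 1.6))$rank_aB, 1L)
  expect_equal(as.character(classify_quadruple(make_quad(1, 1.2, 1.5, 0.9))$label), "sign")   # rank 4
  r2 <- classify_quadruple(make_quad(1, 1.2, 1.5, 1.3), scale = "additive")
  expect_equal(r2$rank_aB, 2L)
  expect_equal(r2$epsilon, 0)
  expect_equal(as.character(r2$label), "none")
  r3 <- classify_quadruple(make_quad(1, 1.2, 1.5, 1.1), scale = "additive")
  expect_equal(r3$rank_aB, 3L)
  expect_equal(r3$epsilon, 0.2)
  expect_equal(as.character(r3$label), "synergistic")
  # tied fitnesses are an explicit degenerate outcome
  rt <- classify_quadruple(make_quad(1, 1.2, 1.5, 1.2))
  expect_true(rt$degenerate)
  expect_equal(as.character(rt$label), "degenerate")
  expect_true(is.na(rt$rank_aB))
  # the walk convention is enforced
  expect_error(classify_quadruple(make_quad(2, 1.2, 1.5, 1.3)), "walk convention")
})

test_that("rank classifier agrees with the sign-change-across-backgrounds oracle", {
  set.seed(23)
  q <- random_walk_quadruples(4000)
  got <- epiwalk:::classify_core(q$w_ab, q$w_Ab, q$w_AB, q$w_aB)
  want <- oracle_sign_epistasis(q$w_ab, q$w_Ab, q$w_aB, q$w_AB)
  expect_equal(got$label_mult == "sign", want)
  expect_equal(got$label_add == "sign", want)
})

test_that("classification is invariant under exchanging the focal loci", {
  set.seed(24)
  q <- random_walk_quadruples(500)
  a <- epiwalk:::classify_core(q$w_ab, q$w_Ab, q$w_AB, q$w_aB)
  # swapping the roles of Ab and aB re-imposes the convention with the other
  # single mutant on the path; valid only when the chain still holds
  ok <- q$w_ab < q$w_aB & q$w_aB < q$w_AB
  b <- epiwalk:::classify_core(q$w_ab[ok], q$w_aB[ok], q$w_AB[ok], q$w_Ab[ok])
  expect_equal(b$label_mult == "sign", (a$label_mult == "sign")[ok])
  expect_equal(b$eps_mult, a$eps_mult[ok])
})

test_that("stratified quadruples respect the stratum and the convention", {
  lnd <- nk_landscape(L = 10, K = 7, seed = 25)
  bounds <- quartile_bounds(lnd)
  edges <- c(-Inf, bounds$bounds, Inf)
  set.seed(26)
  for (qt in c(1L, 4L)) {
    smp <- sample_quadruples(lnd, 50, quartile = qt, bounds = bounds)
    expect_true(all(smp$w_ab > edges[qt] & smp$w_ab <= edges[qt + 1]))
    expect_true(all(smp$w_ab < smp$w_Ab & smp$w_Ab < smp$w_AB))
    expect_true(all(smp$focal_1 < smp$focal_2))
  }
})

test_that("focal locus pairs are uniform over unordered pairs", {
  # pooled over fresh uncorrelated landscapes: on any one fixed landscape the
  # number of valid quadruples per locus pair fluctuates around its mean, so
  # pair uniformity is a property of the sampling scheme, not of one table
  set.seed(28)
  smp <- dplyr::bind_rows(lapply(1:30, function(i) {
    sample_quadruples(nk_landscape(L = 6, K = 5, seed = 2700 + i), 100)
  }))
  tab <- table(paste(smp$focal_1, smp$focal_2))
  expect_equal(length(tab), choose(6, 2))
  expect_gt(chisq.test(tab)$p.value, 0.01)
})
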