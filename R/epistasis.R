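# Quadruple extraction and epistasis classification. A quadruple is the set
# {ab, Ab, aB, AB} of genotypes differing at two focal loci. Walk-derived
# quadruples satisfy w_ab < w_Ab < w_AB by construction; classification is
# by the fitness rank of the off-path genotype aB among the four: ranked
# first or fourth means sign epistasis, ranked second or third means
# non-sign epistasis whose type follows the sign of epsilon.

#' Construct a genotype quadruple
#'
#' @param ab,Ab,AB Genotypes in walk order (each one mutation apart,
#'   flipping two distinct focal loci overall).
#' @param lnd Fitness landscape supplying the four fitness values.
#' @return A `quadruple`: list with `genotypes` (4 x L matrix, rows
#'   ab/Ab/aB/AB), `w` (named fitnesses), `focal` (the two focal loci).
#' @export
quadruple <- function(ab, Ab, AB, lnd) {
  ab <- as_genotype(ab, lnd$L)
  Ab <- as_genotype(Ab, lnd$L)
  AB <- as_genotype(AB, lnd$L)
  aB <- complement_genotype(ab, Ab, AB)
  G <- rbind(ab = ab, Ab = Ab, aB = aB, AB = AB)
  w <- setNames(fitness_many(lnd, G), rownames(G))
  focal <- sort(c(which(ab != Ab), which(Ab != AB)))
  structure(list(genotypes = G, w = w, focal = focal), class = "quadruple")
}

#' @export
print.quadruple <- function(x, ...) {
  cat("<genotype quadruple>  focal loci:", paste(x$focal, collapse = ", "), "\n")
  for (r in rownames(x$genotypes)) {
    cat(sprintf("  %-3s %s  w = %.6f\n", r, gt_string(x$genotypes[r, ]), x$w[[r]]))
  }
  invisible(x)
}

#' Quadruple spanned by two consecutive walk steps
#'
#' Positions `t`, `t + 1`, `t + 2` of the walk give `ab`, `Ab`, `AB`; the
#' fourth genotype `aB` is their allele-wise complement. The walk's strict
#' fitness increase guarantees `w_ab < w_Ab < w_AB`.
#'
#' @param walk A [run_walk()] result.
#' @param t 1-based position of the first genotype of the window.
#' @param lnd The landscape the walk was simulated on.
#' @return A `quadruple`.
#' @export
quadruple_from_walk <- function(walk, t, lnd) {
  G <- attr(walk, "genotype_matrix")
  if (is.null(G)) G <- do.call(rbind, lapply(walk$genotype, gt_parse))
  if (t < 1 || t + 2 > nrow(G)) {
    stop("walk has no quadruple window starting at position ", t, call. = FALSE)
  }
  quadruple(G[t, ], G[t + 1, ], G[t + 2, ], lnd)
}

#' Epistasis measure of a quadruple
#'
#' On the multiplicative scale,
#' `epsilon = ln w_ab + ln w_AB - ln w_Ab - ln w_aB` (same sign as
#' `w_ab * w_AB - w_Ab * w_aB`); on the additive scale,
#' `epsilon = w_ab + w_AB - w_Ab - w_aB`. Positive epsilon means the double
#' mutant exceeds the null (multiplicative or additive) expectation —
#' synergistic epistasis; negative means antagonistic.
#'
#' @param q A `quadruple`.
#' @param scale `"multiplicative"` or `"additive"`.
#' @return The epsilon value.
#' @export
epsilon <- function(q, scale = c("multiplicative", "additive")) {
  scale <- match.arg(scale)
  w <- q$w
  if (scale == "multiplicative") {
    if (any(w <= 0)) stop("multiplicative epsilon needs positive fitnesses", call. = FALSE)
    log(w[["ab"]]) + log(w[["AB"]]) - log(w[["Ab"]]) - log(w[["aB"]])
  } else {
    w[["ab"]] + w[["AB"]] - w[["Ab"]] - w[["aB"]]
  }
}

# Vectorized classification core shared by the walk and sampling pipelines.
# Returns rank of aB (1 = fittest), both epsilon scales, a degeneracy flag
# (any exact tie among the four fitnesses), and labels on both scales.
classify_core <- function(w_ab, w_Ab, w_AB, w_aB, eps_tol = 1e-9) {
  degenerate <- (w_aB == w_ab) | (w_aB == w_Ab) | (w_aB == w_AB) |
    (w_ab == w_Ab) | (w_ab == w_AB) | (w_Ab == w_AB)
  rank_aB <- 1L + (w_ab > w_aB) + (w_Ab > w_aB) + (w_AB > w_aB)
  eps_mult <- log(w_ab) + log(w_AB) - log(w_Ab) - log(w_aB)
  eps_add <- w_ab + w_AB - w_Ab - w_aB
  tibble::tibble(
    rank_aB = ifelse(degenerate, NA_integer_, rank_aB),
    eps_mult = eps_mult,
    eps_add = eps_add,
    degenerate = degenerate,
    label_mult = epistasis_label(rank_aB, eps_mult, degenerate, eps_tol),
    label_add = epistasis_label(rank_aB, eps_add, degenerate, eps_tol)
  )
}

# Label from the rank of aB and an epsilon value. Rank 1 or 4 -> sign;
# rank 2 or 3 -> synergistic/antagonistic/none by the sign of epsilon.
# |eps| <= eps_tol counts as no epistasis: a multiplicative (or additive)
# landscape evaluated in floating point yields eps ~ 1e-16, never exactly 0,
# while genuine epistasis on these landscape families is orders larger.
epistasis_label <- function(rank_aB, eps, degenerate = FALSE, eps_tol = 1e-9) {
  out <- rep("none", length(eps))
  out[rank_aB %in% c(1L, 4L)] <- "sign"
  nonsign <- rank_aB %in% c(2L, 3L)
  out[nonsign & eps > eps_tol] <- "synergistic"
  out[nonsign & eps < -eps_tol] <- "antagonistic"
  out[degenerate] <- "degenerate"
  factor(out, levels = c("sign", "synergistic", "antagonistic", "none", "degenerate"))
}

#' Classify a quadruple's epistasis
#'
#' Requires the walk convention `w_ab < w_Ab < w_AB`. The rank of `aB` among
#' the four fitnesses determines sign epistasis (rank 1 or 4); otherwise the
#' sign of epsilon on the requested scale splits synergistic from
#' antagonistic (`|epsilon| <= 1e-9` counts as `"none"`, so multiplicative
#' or additive landscapes evaluated in floating point classify cleanly).
#' Exact fitness ties yield an explicit `"degenerate"` label with `NA` rank
#' rather than an arbitrary ordering.
#'
#' @param q A `quadruple` with `w_ab < w_Ab < w_AB`.
#' @param scale Scale whose epsilon fills the `epsilon` and `label` columns;
#'   both scales are always reported.
#' @return A one-row tibble: `rank_aB`, `eps_mult`, `eps_add`, `epsilon`,
#'   `label`, `degenerate`.
#' @export
#' @examples
#' lnd <- nk_landscape(L = 6, K = 5, seed = 3)
#' w <- run_walk(lnd, sample_low_fitness_genotype(lnd), seed = 4)
#' if (nrow(w) >= 3) classify_quadruple(quadruple_from_walk(w, 1, lnd))
classify_quadruple <- function(q, scale = c("multiplicative", "additive")) {
  scale <- match.arg(scale)
  w <- q$w
  if (!(w[["ab"]] < w[["Ab"]] && w[["Ab"]] < w[["AB"]])) {
    stop("quadruple violates the walk convention w_ab < w_Ab < w_AB", call. = FALSE)
  }
  res <- classify_core(w[["ab"]], w[["Ab"]], w[["AB"]], w[["aB"]])
  res$epsilon <- if (scale == "multiplicative") res$eps_mult else res$eps_add
  res$label <- if (scale == "multiplicative") res$label_mult else res$label_add
  res[, c("rank_aB", "eps_mult", "eps_add", "epsilon", "label", "degenerate")]
}

# Epistasis records for every two-step window of a walk: vectorized over
# windows. Returns zero rows for walks shorter than three genotypes.
walk_records <- function(walk, lnd) {
  G <- attr(walk, "genotype_matrix")
  n <- nrow(G)
  if (n < 3L) {
    return(tibble::tibble(
      step = integer(0), w_ab = double(0), w_Ab = double(0),
      w_AB = double(0), w_aB = double(0), rank_aB = integer(0),
      eps_mult = double(0), eps_add = double(0), degenerate = logical(0),
      label_mult = factor(levels = levels(epistasis_label(integer(0), double(0)))),
      label_add = factor(levels = levels(epistasis_label(integer(0), double(0))))
    ))
  }
  t <- seq_len(n - 2L)
  AB_xor <- (G[t, , drop = FALSE] + G[t + 1L, , drop = FALSE] +
               G[t + 2L, , drop = FALSE]) %% 2L
  w_aB <- fitness_many(lnd, AB_xor)
  w <- walk$fitness
  res <- classify_core(w[t], w[t + 1L], w[t + 2L], w_aB)
  tibble::tibble(
    step = t,
    w_ab = w[t], w_Ab = w[t + 1L], w_AB = w[t + 2L], w_aB = w_aB,
    rank_aB = res$rank_aB, eps_mult = res$eps_mult, eps_add = res$eps_add,
    degenerate = res$degenerate,
    label_mult = res$label_mult, label_add = res$label_add
  )
}

#' Enumerate every two-locus quadruple of a landscape
#'
#' Walks all unordered focal-locus pairs and all 2^(L-2) backgrounds,
#' reading the four corner fitnesses from the full fitness table. Corners
#' are labelled canonically by the focal alleles (`w00` = both ancestral,
#' `w11` = both derived), so `eps_*` here is the epistasis measure of the
#' Fig-1-style quadruple based at `w00`; its magnitude is
#' labelling-invariant.
#'
#' @param lnd A fitness landscape (L small enough to tabulate).
#' @return A tibble with `locus_1`, `locus_2`, the four corner fitnesses,
#'   `eps_mult`, and `eps_add`; `choose(L, 2) * 2^(L-2)` rows.
#' @export
enumerate_quadruples <- function(lnd) {
  L <- lnd$L
  W <- fitness_table(lnd)
  idx <- 0:(2L^L - 1L)
  pairs <- utils::combn(L, 2L)
  res <- vector("list", ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1L, p]
    j <- pairs[2L, p]
    wi <- 2L^(L - i)
    wj <- 2L^(L - j)
    base <- idx[bitwAnd(idx, wi) == 0L & bitwAnd(idx, wj) == 0L]
    w00 <- W[base + 1L]
    w10 <- W[base + wi + 1L]
    w01 <- W[base + wj + 1L]
    w11 <- W[base + wi + wj + 1L]
    res[[p]] <- tibble::tibble(
      locus_1 = i, locus_2 = j,
      w00 = w00, w10 = w10, w01 = w01, w11 = w11,
      eps_mult = log(w00) + log(w11) - log(w10) - log(w01),
      eps_add = w00 + w11 - w10 - w01
    )
  }
  dplyr::bind_rows(res)
}

#' Sample walk-convention quadruples, optionally stratified by quartile
#'
#' Draws candidate triples — a base genotype `ab` (uniform, or
#' rejection-sampled into the requested fitness quartile of the landscape)
#' together with an ordered pair of distinct focal loci, where `Ab` flips
#' the first focal locus and `AB` both — and accepts a candidate when the
#' walk convention `w_ab < w_Ab < w_AB` holds. On failure the whole
#' candidate (base and loci) is redrawn, so accepted quadruples are uniform
#' over all valid (base, loci, orientation) triples and the off-path
#' genotype `aB` is conditioned on nothing beyond the convention.
#'
#' @param lnd A fitness landscape.
#' @param n Number of quadruples.
#' @param quartile Optional quartile 1-4 that `w_ab` must fall in
#'   (1 = lowest); `NULL` leaves `ab` unconditioned.
#' @param bounds Optional precomputed [quartile_bounds()].
#' @param max_rounds Rejection-round budget before failing.
#' @return A tibble with `w_ab`, `w_Ab`, `w_AB`, `w_aB`, focal loci,
#'   classification columns as in [classify_quadruple()], and `quartile`.
#' @export
sample_quadruples <- function(lnd, n, quartile = NULL, bounds = NULL,
                              max_rounds = 5000L) {
  L <- lnd$L
  if (!is.null(quartile)) {
    stopifnot(quartile %in% 1:4)
    bounds <- bounds %||% quartile_bounds(lnd)
    edges <- c(-Inf, bounds$bounds, Inf)
    lo <- edges[quartile]
    hi <- edges[quartile + 1L]
  }
  draw_ab <- function(m) {
    # uniform genotypes, rejection-filtered into the stratum when requested
    out_G <- NULL
    out_w <- numeric(0)
    guard <- 0L
    while (length(out_w) < m) {
      if ((guard <- guard + 1L) > 2000L) {
        stop("rejection budget exceeded while sampling base genotypes", call. = FALSE)
      }
      b <- max(2L * m, 64L)
      G <- matrix(sample(c(0L, 1L), b * L, replace = TRUE), ncol = L)
      w <- fitness_many(lnd, G)
      if (!is.null(quartile)) {
        keep <- which(w > lo & w <= hi)
        G <- G[keep, , drop = FALSE]
        w <- w[keep]
      }
      out_G <- rbind(out_G, G)
      out_w <- c(out_w, w)
    }
    list(G = out_G[seq_len(m), , drop = FALSE], w = out_w[seq_len(m)])
  }

  got <- 0L
  res <- vector("list", 0L)
  rounds <- 0L
  p_hat <- 1 / 6  # chain acceptance for exchangeable fitnesses; adapted below
  while (got < n) {
    if ((rounds <- rounds + 1L) > max_rounds) {
      stop("rejection budget exceeded while sampling quadruples", call. = FALSE)
    }
    m <- min(50000L, max(64L, ceiling(1.3 * (n - got) / max(p_hat, 0.01))))
    ab <- draw_ab(m)
    i <- sample.int(L, m, replace = TRUE)
    j <- sample.int(L - 1L, m, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j)  # ordered distinct pair (i, j)
    rows <- seq_len(m)
    G_Ab <- ab$G; G_Ab[cbind(rows, i)] <- 1L - G_Ab[cbind(rows, i)]
    G_AB <- G_Ab; G_AB[cbind(rows, j)] <- 1L - G_AB[cbind(rows, j)]
    wAb <- fitness_many(lnd, G_Ab)
    wAB <- fitness_many(lnd, G_AB)
    ok <- which(ab$w < wAb & wAb < wAB)
    p_hat <- (length(ok) + 1) / (m + 6)
    if (length(ok)) {
      ok <- head(ok, n - got)
      G_aB <- ab$G[ok, , drop = FALSE]
      G_aB[cbind(seq_along(ok), j[ok])] <- 1L - G_aB[cbind(seq_along(ok), j[ok])]
      res[[length(res) + 1L]] <- tibble::tibble(
        w_ab = ab$w[ok], w_Ab = wAb[ok], w_AB = wAB[ok],
        w_aB = fitness_many(lnd, G_aB),
        focal_1 = pmin(i[ok], j[ok]), focal_2 = pmax(i[ok], j[ok])
      )
      got <- got + length(ok)
    }
  }
  out <- dplyr::bind_rows(res)
  cls <- classify_core(out$w_ab, out$w_Ab, out$w_AB, out$w_aB)
  out <- dplyr::bind_cols(out, cls)
  out$quartile <- if (is.null(quartile)) NA_integer_ else as.integer(quartile)
  out
}

#' Sample a single quartile-stratified quadruple
#'
#' Convenience wrapper around [sample_quadruples()] returning a `quadruple`
#' object whose base genotype's fitness lies in the requested quartile.
#'
#' @inheritParams sample_quadruples
#' @return A one-row tibble as from [sample_quadruples()].
#' @export
sample_stratified_quadruple <- function(lnd, quartile, bounds = NULL) {
  sample_quadruples(lnd, 1L, quartile = quartile, bounds = bounds)
}
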