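# Fitness landscape constructors. Both families map all 2^L biallelic
# genotypes to strictly positive fitnesses; ruggedness is tuned by K (NK)
# or by the slope:noise ratio (Rough Mount Fuji).

#' Construct an NK fitness landscape
#'
#' Each locus contributes a value that depends on its own allele and on the
#' alleles at K other loci, drawn uniformly without replacement per locus.
#' Every contribution is an independent Uniform(c_min, c_max) draw; the
#' fitness of a genotype is the geometric mean of its L locus contributions,
#' so all fitnesses lie in [c_min, c_max]. K = 0 gives a purely
#' multiplicative (epistasis-free) landscape; K = L - 1 makes genotype
#' fitnesses mutually independent.
#'
#' The positive floor `c_min` bounds selection coefficients, which are
#' fitness ratios, away from infinity.
#'
#' @param L Locus count.
#' @param K Number of interacting loci per locus, in `[0, L - 1]`.
#' @param c_min,c_max Contribution bounds, `0 < c_min < c_max`.
#' @param seed Optional integer seed; when supplied the landscape is built in
#'   a local RNG scope and is bit-reproducible.
#' @return An object of class `c("nk_landscape", "fitness_landscape")`.
#' @export
#' @examples
#' lnd <- nk_landscape(L = 5, K = 2, seed = 1)
#' fitness(lnd, c(0, 1, 0, 1, 1))
nk_landscape <- function(L = 15, K = 10, c_min = 0.1, c_max = 1.0, seed = NULL) {
  if (K < 0 || K > L - 1) stop("K must lie in [0, L - 1]", call. = FALSE)
  if (!(c_min > 0 && c_min < c_max)) stop("need 0 < c_min < c_max", call. = FALSE)
  build <- function() {
    nbhd <- lapply(seq_len(L), function(i) {
      others <- setdiff(seq_len(L), i)
      if (K == 0) integer(0) else sort(sample(others, K))
    })
    contrib <- lapply(seq_len(L), function(i) runif(2L^(K + 1L), c_min, c_max))
    structure(
      list(model = "nk", L = as.integer(L), K = as.integer(K),
           c_min = c_min, c_max = c_max,
           neighborhoods = nbhd, contributions = contrib),
      class = c("nk_landscape", "fitness_landscape")
    )
  }
  if (is.null(seed)) build() else withr::with_seed(as.integer(seed), build())
}

#' Construct an additive Rough Mount Fuji landscape
#'
#' Each genotype receives a deterministic component `slope * d(g)`, where
#' `d(g)` counts derived alleles, plus an independent Uniform(noise) draw;
#' the raw values are then affinely rescaled so the table's minimum and
#' maximum equal `w_range`. High `slope` means a low noise-to-deterministic
#' ratio (a smooth, Fuji-like landscape); `slope = 0` is the
#' house-of-cards limit of i.i.d. fitnesses.
#'
#' @param L Locus count (the full 2^L table is stored).
#' @param slope Nonnegative additive increment per derived allele
#'   (pre-rescaling units).
#' @param noise Length-2 bounds of the uniform noise; zero width is allowed
#'   when `slope > 0` and yields a noise-free additive landscape.
#' @param w_range Length-2 post-transform fitness range, `0 < w_min < w_max`.
#' @param seed Optional integer seed.
#' @return An object of class `c("rmf_landscape", "fitness_landscape")`.
#' @export
#' @examples
#' lnd <- rmf_landscape(L = 6, slope = 0.25, seed = 1)
#' range(fitness_table(lnd))
rmf_landscape <- function(L = 15, slope = 0.25, noise = c(0, 1),
                          w_range = c(1, 2), seed = NULL) {
  if (slope < 0) stop("slope must be nonnegative", call. = FALSE)
  if (length(noise) != 2L || noise[1] > noise[2]) {
    stop("noise must be increasing bounds (noise_low <= noise_high)", call. = FALSE)
  }
  if (length(w_range) != 2L || !(w_range[1] > 0 && w_range[1] < w_range[2])) {
    stop("w_range must satisfy 0 < w_min < w_max", call. = FALSE)
  }
  build <- function() {
    G <- all_genotypes(L)
    d <- rowSums(G)
    raw <- slope * d + runif(nrow(G), noise[1], noise[2])
    rng <- range(raw)
    if (rng[1] == rng[2]) {
      stop("degenerate raw fitness range: all values equal; cannot rescale",
           call. = FALSE)
    }
    tab <- w_range[1] + (raw - rng[1]) / (rng[2] - rng[1]) * diff(w_range)
    structure(
      list(model = "rmf", L = as.integer(L), slope = slope,
           noise = noise, w_range = w_range, table = tab),
      class = c("rmf_landscape", "fitness_landscape")
    )
  }
  if (is.null(seed)) build() else withr::with_seed(as.integer(seed), build())
}

#' @export
print.fitness_landscape <- function(x, ...) {
  if (x$model == "nk") {
    cat(sprintf("<NK fitness landscape>  L = %d, K = %d, contributions U(%g, %g)\n",
                x$L, x$K, x$c_min, x$c_max))
  } else {
    cat(sprintf("<Rough Mt. Fuji landscape>  L = %d, slope = %g, noise U(%g, %g), fitness in [%g, %g]\n",
                x$L, x$slope, x$noise[1], x$noise[2], x$w_range[1], x$w_range[2]))
  }
  invisible(x)
}

#' Genotype fitness
#'
#' `fitness()` evaluates a single genotype; `fitness_many()` evaluates each
#' row of a genotype matrix (the fast path used by the simulators);
#' `fitness_table()` returns the full vector of 2^L fitnesses indexed by the
#' genotype's integer encoding (bitstring read as a binary number, plus 1).
#'
#' @param lnd A fitness landscape.
#' @param g A genotype.
#' @return A positive fitness value.
#' @export
fitness <- function(lnd, g) {
  fitness_many(lnd, matrix(as_genotype(g, lnd$L), nrow = 1L))[1L]
}

#' @rdname fitness
#' @param G Integer 0/1 matrix with one genotype per row.
#' @export
fitness_many <- function(lnd, G) {
  UseMethod("fitness_many")
}

#' @export
fitness_many.nk_landscape <- function(lnd, G) {
  K <- lnd$K
  w <- 2^(0:K)
  acc <- numeric(nrow(G))
  for (i in seq_len(lnd$L)) {
    cols <- c(i, lnd$neighborhoods[[i]])
    idx <- as.integer(G[, cols, drop = FALSE] %*% w) + 1L
    acc <- acc + log(lnd$contributions[[i]][idx])
  }
  exp(acc / lnd$L)
}

#' @export
fitness_many.rmf_landscape <- function(lnd, G) {
  lnd$table[genotype_index(G)]
}

#' @rdname fitness
#' @export
fitness_table <- function(lnd) {
  UseMethod("fitness_table")
}

#' @export
fitness_table.rmf_landscape <- function(lnd) {
  lnd$table
}

#' @export
fitness_table.nk_landscape <- function(lnd) {
  fitness_many(lnd, all_genotypes(lnd$L))
}

#' Is a genotype a local fitness optimum?
#'
#' @inheritParams fitness
#' @return `TRUE` when no mutational neighbor is strictly fitter.
#' @export
is_local_optimum <- function(lnd, g) {
  g <- as_genotype(g, lnd$L)
  all(fitness_many(lnd, hamming_neighbors(g)) <= fitness(lnd, g))
}
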