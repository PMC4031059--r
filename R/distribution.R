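# Fitness-distribution summaries: Gaussian (CLT) approximation of the NK
# log-fitness distribution, quartile boundaries, low-fitness-tail start
# sampling, and the neighbor-fitness correlation diagnostic.

# Closed-form moments of ln U for U ~ Uniform(a, b):
#   E[ln U]     = (b ln b - a ln a)/(b - a) - 1
#   E[(ln U)^2] = [x((ln x)^2 - 2 ln x + 2)]_a^b / (b - a)
log_uniform_moments <- function(a, b) {
  F1 <- function(x) x * (log(x) - 1)
  F2 <- function(x) x * (log(x)^2 - 2 * log(x) + 2)
  m1 <- (F1(b) - F1(a)) / (b - a)
  m2 <- (F2(b) - F2(a)) / (b - a)
  list(mean = m1, var = m2 - m1^2)
}

#' Moments of NK log-fitness under the CLT approximation
#'
#' Log-fitness of an NK genotype is the mean of L i.i.d. log-uniform
#' contribution terms, so its mean is `E[ln U]` and its standard deviation
#' `SD[ln U] / sqrt(L)` for `U ~ Uniform(c_min, c_max)`; both are computed
#' from the closed-form log-uniform moments.
#'
#' @param L Locus count.
#' @param c_min,c_max Contribution bounds.
#' @return A list with `mu_log` and `sigma_log`.
#' @export
#' @examples
#' nk_log_fitness_moments(15, 0.1, 1.0)
nk_log_fitness_moments <- function(L, c_min = 0.1, c_max = 1.0) {
  if (!(c_min > 0 && c_min < c_max)) stop("need 0 < c_min < c_max", call. = FALSE)
  m <- log_uniform_moments(c_min, c_max)
  list(mu_log = m$mean, sigma_log = sqrt(m$var) / sqrt(L))
}

#' Fitness quartile boundaries of a landscape
#'
#' Theoretical mode (NK only) places Gaussian quantiles on the CLT
#' approximation of log-fitness and exponentiates; empirical mode takes
#' sample quantiles (linear interpolation, `type = 7`) of the full fitness
#' table. Theoretical is the default for NK, empirical for Rough Mt. Fuji,
#' where the full table is always at hand.
#'
#' @param lnd A fitness landscape.
#' @param mode `"theoretical"` or `"empirical"`.
#' @return A `fitness_summary` list: `mu_log`, `sigma_log`, `bounds`
#'   (the 25/50/75 percent fitness boundaries, strictly increasing),
#'   and `source`.
#' @export
#' @examples
#' quartile_bounds(nk_landscape(L = 8, K = 3, seed = 1))
quartile_bounds <- function(lnd, mode = NULL) {
  mode <- mode %||% if (lnd$model == "nk") "theoretical" else "empirical"
  mode <- match.arg(mode, c("theoretical", "empirical"))
  if (mode == "theoretical") {
    if (lnd$model != "nk") {
      stop("theoretical quartile bounds are defined for NK landscapes only",
           call. = FALSE)
    }
    m <- nk_log_fitness_moments(lnd$L, lnd$c_min, lnd$c_max)
    bounds <- exp(qnorm(c(0.25, 0.5, 0.75), m$mu_log, m$sigma_log))
    mu <- m$mu_log
    sig <- m$sigma_log
  } else {
    tab <- fitness_table(lnd)
    bounds <- unname(quantile(tab, c(0.25, 0.5, 0.75), type = 7))
    mu <- mean(log(tab))
    sig <- sd(log(tab))
  }
  structure(
    list(mu_log = mu, sigma_log = sig, bounds = bounds, source = mode),
    class = "fitness_summary"
  )
}

#' @export
print.fitness_summary <- function(x, ...) {
  cat(sprintf("<fitness summary (%s)>  mu_log = %.4f, sigma_log = %.4f\n",
              x$source, x$mu_log, x$sigma_log))
  cat(sprintf("  quartile bounds: %.4f | %.4f | %.4f\n",
              x$bounds[1], x$bounds[2], x$bounds[3]))
  invisible(x)
}

#' Sample a low-fitness starting genotype
#'
#' Adaptive walks start in the landscape's low-fitness tail. For NK
#' landscapes, uniform random genotypes are rejection-sampled until the
#' log-fitness falls below `mu_log - 1.5 * sigma_log` of the theoretical
#' (CLT) approximation. For Rough Mt. Fuji landscapes, the start is drawn
#' uniformly among genotypes in the bottom `pnorm(-1.5)` (about 6.68
#' percent) of the empirical fitness table, the Gaussian-equivalent tail
#' mass of the same rule.
#'
#' @param lnd A fitness landscape.
#' @param summary Optional precomputed [quartile_bounds()] summary.
#' @param max_draws Rejection budget before failing (NK mode).
#' @return A genotype satisfying the tail threshold.
#' @export
sample_low_fitness_genotype <- function(lnd, summary = NULL, max_draws = 1e5) {
  if (lnd$model == "nk") {
    summary <- summary %||% quartile_bounds(lnd, "theoretical")
    thr <- summary$mu_log - 1.5 * summary$sigma_log
    drawn <- 0
    batch <- 64L
    while (drawn < max_draws) {
      G <- matrix(sample(c(0L, 1L), batch * lnd$L, replace = TRUE), ncol = lnd$L)
      hit <- which(log(fitness_many(lnd, G)) < thr)
      drawn <- drawn + batch
      if (length(hit)) return(G[hit[1L], ])
    }
    stop("rejection budget exceeded: no genotype below the low-fitness threshold",
         call. = FALSE)
  }
  tab <- fitness_table(lnd)
  thr <- unname(quantile(tab, pnorm(-1.5), type = 7))
  pool <- which(tab <= thr)
  if (!length(pool)) {
    stop("no genotype in the low-fitness tail (constant landscape?)", call. = FALSE)
  }
  all_genotypes(lnd$L)[pool[sample.int(length(pool), 1L)], ]
}

#' Fitness correlation between mutational neighbors
#'
#' Pearson correlation of `(w(g), w(g'))` over sampled pairs, where `g` is
#' uniform on the hypercube and `g'` a uniformly chosen one-mutation
#' neighbor. Decreases with K in NK landscapes and increases with slope in
#' Rough Mt. Fuji landscapes.
#'
#' @param lnd A fitness landscape.
#' @param n_pairs Number of sampled pairs (at least 2).
#' @return Pearson correlation in `[-1, 1]`.
#' @export
neighbor_fitness_correlation <- function(lnd, n_pairs = 1000) {
  if (n_pairs < 2) stop("n_pairs must be at least 2", call. = FALSE)
  L <- lnd$L
  G <- matrix(sample(c(0L, 1L), n_pairs * L, replace = TRUE), ncol = L)
  flip <- sample.int(L, n_pairs, replace = TRUE)
  Gn <- G
  idx <- cbind(seq_len(n_pairs), flip)
  Gn[idx] <- 1L - Gn[idx]
  w <- fitness_many(lnd, G)
  wn <- fitness_many(lnd, Gn)
  if (sd(w) == 0 || sd(wn) == 0) {
    stop("zero fitness variance: constant landscape", call. = FALSE)
  }
  cor(w, wn)
}
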