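# Batch simulation: many landscapes, one or more adaptive walks each,
# epistasis records for every two-step window, and per-landscape control
# genotypes for the percentile-interval analysis.

#' Run configuration for a simulation batch
#'
#' Collects every tunable of a batch run: landscape family and its
#' parameters, ensemble size, walk scheme, start rule, epsilon scale, and
#' the master seed from which all per-landscape and per-walk streams are
#' derived. Defaults mirror the core study design: 1000 NK landscapes with
#' L = 15, K = 10, one SSWM walk per landscape from a low-fitness start.
#'
#' @param model `"nk"` or `"rmf"`.
#' @param L Locus count.
#' @param K NK interaction count (ignored for RMF).
#' @param c_min,c_max NK contribution bounds.
#' @param slope,noise,w_range Rough Mt. Fuji parameters (ignored for NK).
#' @param n_landscapes Landscapes in the ensemble.
#' @param walks_per_landscape Walks simulated per landscape.
#' @param scheme `"sswm"` or `"equal"`.
#' @param start_rule `"low_tail"` (default) or `"uniform"`.
#' @param scale Default epsilon scale for labels: `"multiplicative"` (NK
#'   default) or `"additive"` (RMF default).
#' @param control_n Random control genotypes drawn per landscape.
#' @param master_seed Integer master seed.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(model = c("nk", "rmf"), L = 15, K = 10,
                       c_min = 0.1, c_max = 1.0,
                       slope = 0.25, noise = c(0, 1), w_range = c(1, 2),
                       n_landscapes = 1000, walks_per_landscape = 1,
                       scheme = c("sswm", "equal"),
                       start_rule = c("low_tail", "uniform"),
                       scale = NULL, control_n = 1, master_seed = 1) {
  model <- match.arg(model)
  scheme <- match.arg(scheme)
  start_rule <- match.arg(start_rule)
  scale <- scale %||% if (model == "nk") "multiplicative" else "additive"
  scale <- match.arg(scale, c("multiplicative", "additive"))
  check <- function(ok, field, msg) {
    if (!ok) stop("invalid `", field, "`: ", msg, call. = FALSE)
  }
  check(is.numeric(L) && length(L) == 1 && L >= 2 && L == floor(L), "L",
        "must be an integer >= 2")
  check(is.numeric(n_landscapes) && n_landscapes >= 0 &&
          n_landscapes == floor(n_landscapes), "n_landscapes",
        "must be a nonnegative integer")
  check(walks_per_landscape >= 1, "walks_per_landscape", "must be >= 1")
  check(control_n >= 0, "control_n", "must be >= 0")
  check(is.numeric(master_seed) && length(master_seed) == 1, "master_seed",
        "must be a single integer")
  if (model == "nk") {
    check(K >= 0 && K <= L - 1 && K == floor(K), "K",
          "must be an integer in [0, L - 1]")
    check(c_min > 0 && c_min < c_max, "c_min", "need 0 < c_min < c_max")
  } else {
    check(slope >= 0, "slope", "must be nonnegative")
    check(length(noise) == 2 && noise[1] <= noise[2], "noise",
          "must be increasing bounds")
    check(length(w_range) == 2 && w_range[1] > 0 && w_range[1] < w_range[2],
          "w_range", "need 0 < w_min < w_max")
  }
  structure(
    list(model = model, L = as.integer(L), K = as.integer(K),
         c_min = c_min, c_max = c_max,
         slope = slope, noise = as.numeric(noise), w_range = as.numeric(w_range),
         n_landscapes = as.integer(n_landscapes),
         walks_per_landscape = as.integer(walks_per_landscape),
         scheme = scheme, start_rule = start_rule, scale = scale,
         control_n = as.integer(control_n),
         master_seed = as.integer(master_seed)),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("<epiwalk run config>\n")
  if (x$model == "nk") {
    cat(sprintf("  NK: L = %d, K = %d, contributions U(%g, %g)\n",
                x$L, x$K, x$c_min, x$c_max))
  } else {
    cat(sprintf("  RMF: L = %d, slope = %g, noise U(%g, %g), fitness [%g, %g]\n",
                x$L, x$slope, x$noise[1], x$noise[2], x$w_range[1], x$w_range[2]))
  }
  cat(sprintf("  %d landscapes x %d %s walk(s), %s starts, %s scale, seed %d\n",
              x$n_landscapes, x$walks_per_landscape, x$scheme, x$start_rule,
              x$scale, x$master_seed))
  invisible(x)
}

make_landscape_from_config <- function(config, seed) {
  if (config$model == "nk") {
    nk_landscape(config$L, config$K, config$c_min, config$c_max, seed = seed)
  } else {
    rmf_landscape(config$L, config$slope, config$noise, config$w_range, seed = seed)
  }
}

#' Simulate an ensemble of adaptive walks with epistasis records
#'
#' For each landscape: build it from a derived sub-seed, compute its
#' fitness-distribution summary, draw a starting genotype (low-fitness tail
#' by default), run the walk(s), classify every two-step quadruple window,
#' and draw `control_n` uniform random control genotypes. Landscapes are
#' discarded after use, so ensembles of thousands of L = 15 landscapes fit
#' comfortably in memory.
#'
#' @param config A [run_config()].
#' @return A `walk_ensemble` list with tibbles `walks` (landscape, walk,
#'   position, genotype, fitness), `records` (per-window fitness quadruple
#'   and classification), `controls` (landscape, fitness), and the `config`.
#' @export
#' @examples
#' ens <- simulate_walk_ensemble(run_config(L = 8, K = 5, n_landscapes = 5,
#'                                          master_seed = 1))
#' glance(ens)
simulate_walk_ensemble <- function(config) {
  stopifnot(inherits(config, "run_config"))
  walks_l <- list()
  recs_l <- list()
  ctrl_l <- list()
  for (i in seq_len(config$n_landscapes)) {
    lnd <- make_landscape_from_config(config, derive_seed(config$master_seed, i, 0L))
    summ <- quartile_bounds(lnd)
    for (j in seq_len(config$walks_per_landscape)) {
      wk <- withr::with_seed(derive_seed(config$master_seed, i, j), {
        start <- if (config$start_rule == "low_tail") {
          sample_low_fitness_genotype(lnd, summ)
        } else {
          sample(c(0L, 1L), config$L, replace = TRUE)
        }
        run_walk(lnd, start, scheme = config$scheme)
      })
      wtab <- tibble::as_tibble(wk)
      wtab$landscape <- i
      wtab$walk <- j
      walks_l[[length(walks_l) + 1L]] <- wtab
      rec <- walk_records(wk, lnd)
      if (nrow(rec)) {
        rec$landscape <- i
        rec$walk <- j
        recs_l[[length(recs_l) + 1L]] <- rec
      }
    }
    if (config$control_n > 0) {
      ctrl <- withr::with_seed(derive_seed(config$master_seed, i, 999983L), {
        G <- matrix(sample(c(0L, 1L), config$control_n * config$L, replace = TRUE),
                    ncol = config$L)
        fitness_many(lnd, G)
      })
      ctrl_l[[length(ctrl_l) + 1L]] <- tibble::tibble(landscape = i, fitness = ctrl)
    }
  }
  structure(
    list(
      walks = if (length(walks_l)) dplyr::bind_rows(walks_l) else
        tibble::tibble(position = integer(0), genotype = character(0),
                       fitness = double(0), landscape = integer(0),
                       walk = integer(0)),
      records = if (length(recs_l)) dplyr::bind_rows(recs_l) else
        empty_records_tbl(),
      controls = if (length(ctrl_l)) dplyr::bind_rows(ctrl_l) else
        tibble::tibble(landscape = integer(0), fitness = double(0)),
      config = config
    ),
    class = "walk_ensemble"
  )
}

empty_records_tbl <- function() {
  lv <- c("sign", "synergistic", "antagonistic", "none", "degenerate")
  tibble::tibble(
    step = integer(0), w_ab = double(0), w_Ab = double(0), w_AB = double(0),
    w_aB = double(0), rank_aB = integer(0), eps_mult = double(0),
    eps_add = double(0), degenerate = logical(0),
    label_mult = factor(character(0), levels = lv),
    label_add = factor(character(0), levels = lv),
    landscape = integer(0), walk = integer(0)
  )
}

#' @export
print.walk_ensemble <- function(x, ...) {
  cat(sprintf("<walk ensemble>  %d walks on %d %s landscapes (%s scheme)\n",
              nrow(dplyr::distinct(x$walks, .data$landscape, .data$walk)),
              x$config$n_landscapes, toupper(x$config$model), x$config$scheme))
  cat(sprintf("  %d quadruple records, %d control genotypes\n",
              nrow(x$records), nrow(x$controls)))
  invisible(x)
}
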