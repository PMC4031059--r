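# broom-style accessors for landscapes and ensembles.

#' Tidy a fitness landscape into a genotype-fitness table
#'
#' @param x A fitness landscape.
#' @param ... Unused.
#' @return A tibble with `genotype` (bitstring) and `fitness` for all 2^L
#'   genotypes.
#' @export
tidy.fitness_landscape <- function(x, ...) {
  G <- all_genotypes(x$L)
  tibble::tibble(genotype = gt_strings(G), fitness = fitness_many(x, G))
}

#' One-row summary of a fitness landscape
#'
#' @param x A fitness landscape.
#' @param ... Unused.
#' @return A one-row tibble with the family, its parameters, and the
#'   realized fitness range.
#' @export
glance.fitness_landscape <- function(x, ...) {
  tab <- fitness_table(x)
  tibble::tibble(
    model = x$model,
    L = x$L,
    K = if (x$model == "nk") x$K else NA_integer_,
    slope = if (x$model == "rmf") x$slope else NA_real_,
    n_genotypes = length(tab),
    w_min = min(tab), w_max = max(tab),
    w_mean = mean(tab), w_sd = sd(tab)
  )
}

#' Tidy a walk ensemble into its epistasis records
#'
#' @param x A `walk_ensemble`.
#' @param ... Unused.
#' @return The per-window records tibble.
#' @export
tidy.walk_ensemble <- function(x, ...) {
  x$records
}

#' One-row summary of a walk ensemble
#'
#' @param x A `walk_ensemble`.
#' @param ... Unused.
#' @return A one-row tibble: walk counts, length summaries, and the overall
#'   sign-epistasis fraction on the configured scale.
#' @export
glance.walk_ensemble <- function(x, ...) {
  lens <- x$walks %>%
    dplyr::group_by(.data$landscape, .data$walk) %>%
    dplyr::summarise(len = dplyr::n(), .groups = "drop")
  lc <- label_col(x$config$scale)
  nd <- x$records[!x$records$degenerate, ]
  tibble::tibble(
    n_landscapes = x$config$n_landscapes,
    n_walks = nrow(lens),
    mean_length = mean(lens$len),
    max_length = max(lens$len),
    n_quadruples = nrow(x$records),
    frac_sign = if (nrow(nd)) mean(nd[[lc]] == "sign") else NA_real_
  )
}
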