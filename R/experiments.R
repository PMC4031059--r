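# Aggregation analyses: epistasis frequencies by walk step and by fitness
# quartile, percentile-interval summaries of the mean-regression mechanism,
# and local fitness-graph diagnostics of the ridge effect.

label_col <- function(scale) {
  if (match.arg(scale, c("multiplicative", "additive")) == "multiplicative") {
    "label_mult"
  } else {
    "label_add"
  }
}

freq_table <- function(records, by, scale) {
  lc <- label_col(scale)
  records %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) %>%
    dplyr::summarise(
      n_walks = dplyr::n(),
      n = sum(!.data$degenerate),
      n_degenerate = sum(.data$degenerate),
      count_sign = sum(.data[[lc]] == "sign"),
      count_synergistic = sum(.data[[lc]] == "synergistic"),
      count_antagonistic = sum(.data[[lc]] == "antagonistic"),
      count_none = sum(.data[[lc]] == "none"),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      freq_sign = .data$count_sign / .data$n,
      freq_synergistic = .data$count_synergistic / .data$n,
      freq_antagonistic = .data$count_antagonistic / .data$n,
      freq_none = .data$count_none / .data$n
    )
}

#' Epistasis frequencies by walk step
#'
#' Pools the quadruple record of every walk long enough to have a window at
#' each step index and tabulates the relative frequencies of sign,
#' synergistic, antagonistic, and no epistasis. Degenerate (exactly tied)
#' quadruples are excluded from the frequency denominator and reported in
#' their own column. The number of contributing walks is non-increasing in
#' the step index, since walks stop at local optima.
#'
#' @param x A `walk_ensemble` or its `records` tibble.
#' @param scale Epsilon scale used for the labels.
#' @return A tibble of class `step_freq`: one row per step with counts and
#'   frequencies per class, `n_walks` surviving to that step, and
#'   `n_degenerate`.
#' @export
epistasis_by_step <- function(x, scale = c("multiplicative", "additive")) {
  scale <- match.arg(scale)
  records <- if (inherits(x, "walk_ensemble")) x$records else x
  out <- freq_table(records, "step", scale)
  class(out) <- c("step_freq", class(out))
  attr(out, "scale") <- scale
  out
}

#' Epistasis frequencies by fitness quartile
#'
#' Samples walk-convention quadruples stratified by the fitness quartile of
#' the base genotype `ab` across a fresh ensemble of landscapes and
#' tabulates class frequencies per quartile. This is the static mirror of
#' [epistasis_by_step()]: if the changing epistasis pattern along walks is
#' regression to the mean, the same trends must appear when stratifying by
#' base fitness alone, without any walk.
#'
#' @param config A [run_config()]; `n_landscapes` landscapes are generated
#'   and each contributes equally to every stratum.
#' @param n_per_stratum Quadruples per quartile (pooled over landscapes).
#' @param scale Epsilon scale used for the labels.
#' @return A tibble of class `quartile_freq`, one row per quartile.
#' @export
epistasis_by_quartile <- function(config, n_per_stratum = 2000,
                                  scale = c("multiplicative", "additive")) {
  scale <- match.arg(scale)
  stopifnot(inherits(config, "run_config"), n_per_stratum >= 1)
  n_lnd <- max(1L, config$n_landscapes)
  per <- diff(round(seq(0, n_per_stratum, length.out = n_lnd + 1L)))
  recs <- list()
  for (i in seq_len(n_lnd)) {
    if (per[i] == 0) next
    lnd <- make_landscape_from_config(config, derive_seed(config$master_seed, i, 0L))
    bounds <- quartile_bounds(lnd)
    recs[[i]] <- withr::with_seed(derive_seed(config$master_seed, i, 424243L), {
      dplyr::bind_rows(lapply(1:4, function(q) {
        sample_quadruples(lnd, per[i], quartile = q, bounds = bounds)
      }))
    })
  }
  out <- freq_table(dplyr::bind_rows(recs), "quartile", scale)
  out$n_walks <- NULL
  class(out) <- c("quartile_freq", class(out))
  attr(out, "scale") <- scale
  out
}

#' Antagonistic-to-synergistic count ratio
#'
#' @param freq A `step_freq` or `quartile_freq` table.
#' @return The input with an `ant_syn_ratio` column
#'   (`count_antagonistic / count_synergistic`; `NaN`/`Inf` where the
#'   synergistic count is zero).
#' @export
ant_syn_ratio <- function(freq) {
  dplyr::mutate(freq, ant_syn_ratio = .data$count_antagonistic / .data$count_synergistic)
}

#' Percentile intervals of quadruple fitnesses across walks
#'
#' For the early window (walk positions 1-3) or late window (positions
#' 4-6), computes the 2.5, 50, and 97.5 fitness percentiles across walks
#' for each quadruple role — the on-path genotypes `ab`, `Ab`, `AB`, the
#' off-path complement `aB` — and for the random-genotype control. The
#' early window shows `ab` pinned in the low-fitness tail and `aB` near the
#' control (regression toward the mean from below); in the late window all
#' on-path genotypes sit high and `aB` regresses down below `AB`, the ridge
#' signature that produces sign epistasis.
#'
#' @param ensemble A `walk_ensemble` with control genotypes.
#' @param window `"early"` (positions 1-3) or `"late"` (positions 4-6);
#'   walks too short for the window are dropped.
#' @return A tibble of class `interval_set`: `role`, `p2.5`, `median`,
#'   `p97.5`, `n`; attribute `window`.
#' @export
mean_regression_intervals <- function(ensemble, window = c("early", "late")) {
  window <- match.arg(window)
  t0 <- if (window == "early") 1L else 4L
  rec <- dplyr::filter(ensemble$records, .data$step == t0)
  if (nrow(rec) < 2) {
    stop("insufficient data: fewer than 2 walks reach the ", window,
         " window", call. = FALSE)
  }
  pct <- function(x) unname(quantile(x, c(0.025, 0.5, 0.975), type = 7))
  roles <- list(ab = rec$w_ab, Ab = rec$w_Ab, AB = rec$w_AB, aB = rec$w_aB,
                control = ensemble$controls$fitness)
  roles <- roles[vapply(roles, length, 1L) > 0]
  out <- purrr::imap_dfr(roles, function(v, nm) {
    p <- pct(v)
    tibble::tibble(role = nm, `p2.5` = p[1], median = p[2], `p97.5` = p[3],
                   n = length(v))
  })
  out$role <- factor(out$role, levels = c("ab", "Ab", "AB", "aB", "control"))
  class(out) <- c("interval_set", class(out))
  attr(out, "window") <- window
  out
}

#' Count in- and out-arrows at a genotype
#'
#' In the fitness graph, each of the L edges at a genotype points toward
#' the fitter endpoint. `n_in` counts neighbors with lower fitness (arrows
#' pointing in), `n_out` neighbors with higher fitness; exact ties are
#' counted separately. A local optimum has `n_out = 0`; along a late-stage
#' walk on a rugged landscape the mean `n_in / L` exceeds the
#' random-genotype expectation of 1/2 — the ridge effect.
#'
#' @param lnd A fitness landscape.
#' @param g A genotype.
#' @return A one-row tibble: `n_in`, `n_out`, `n_tie`.
#' @export
arrow_summary <- function(lnd, g) {
  g <- as_genotype(g, lnd$L)
  w0 <- fitness(lnd, g)
  w <- fitness_many(lnd, hamming_neighbors(g))
  tibble::tibble(n_in = sum(w < w0), n_out = sum(w > w0), n_tie = sum(w == w0))
}

#' Export the local fitness subgraph around a walk segment
#'
#' Restricts the fitness graph to the genotypes that differ from the walk's
#' genotype at `from_step` only at the loci mutated during the next
#' `n_steps` steps: a 2^n_steps sub-hypercube. Edges are directed toward
#' higher fitness, walk edges are flagged, and vertices carry the reduced
#' bitstring over the affected loci plus the exact fitness.
#'
#' @param lnd The landscape the walk was simulated on.
#' @param walk A [run_walk()] result covering positions
#'   `from_step ... from_step + n_steps`.
#' @param from_step 1-based walk position anchoring the view.
#' @param n_steps Number of walk steps (mutated loci) to span.
#' @param file Optional path; when given the graph is also written in DOT
#'   format.
#' @return An `igraph` directed graph (invisibly when `file` is given) with
#'   vertex attributes `name` (reduced bitstring), `full` (full bitstring),
#'   `fitness`, `on_walk` (0/1), and edge attributes `walk` and `tie` (0/1).
#' @export
export_local_subgraph <- function(lnd, walk, from_step, n_steps = 5, file = NULL) {
  G <- attr(walk, "genotype_matrix")
  if (from_step < 1 || from_step + n_steps > nrow(G)) {
    stop("walk does not cover ", n_steps, " steps from position ", from_step,
         call. = FALSE)
  }
  seg <- G[from_step:(from_step + n_steps), , drop = FALSE]
  loci <- sort(unique(unlist(lapply(seq_len(n_steps), function(k) {
    which(seg[k, ] != seg[k + 1L, ])
  }))))
  base <- seg[1L, ]
  S <- all_genotypes(length(loci))
  full <- matrix(base, nrow = nrow(S), ncol = lnd$L, byrow = TRUE)
  full[, loci] <- S
  w <- fitness_many(lnd, full)
  red <- gt_strings(S)
  walk_red <- gt_strings(seg[, loci, drop = FALSE])
  # edges between sub-hypercube neighbors, oriented toward higher fitness
  from <- integer(0); to <- integer(0)
  for (l in seq_len(ncol(S))) {
    a <- which(S[, l] == 0L)
    b <- a + 2L^(ncol(S) - l)
    lo <- ifelse(w[a] <= w[b], a, b)
    hi <- ifelse(w[a] <= w[b], b, a)
    from <- c(from, lo); to <- c(to, hi)
  }
  # flags stored as 0/1 so the DOT writer needs no attribute conversion
  tie <- as.integer(w[from] == w[to])
  g <- igraph::graph_from_data_frame(
    data.frame(from = red[from], to = red[to], tie = tie),
    directed = TRUE,
    vertices = data.frame(name = red, full = gt_strings(full),
                          fitness = w, on_walk = as.integer(red %in% walk_red))
  )
  walk_pairs <- paste(walk_red[-length(walk_red)], walk_red[-1L])
  edge_pairs <- paste(red[from], red[to])
  igraph::E(g)$walk <- as.integer(edge_pairs %in% walk_pairs)
  if (!is.null(file)) {
    igraph::write_graph(g, file, format = "dot")
    return(invisible(g))
  }
  g
}
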