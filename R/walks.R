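# Adaptive-walk simulation under the strong-selection-weak-mutation (SSWM)
# origin-fixation model or under equal weighting of all fitter neighbors.

#' Fitter mutational neighbors and their selection coefficients
#'
#' @param lnd A fitness landscape.
#' @param g A genotype.
#' @return A tibble with one row per strictly fitter neighbor, ordered by
#'   flipped locus: `locus`, `genotype` (bitstring), `fitness`, and the
#'   selection coefficient `s = w'/w - 1`. Neighbors with exactly equal
#'   fitness are excluded (ties are never beneficial).
#' @export
fitter_neighbors <- function(lnd, g) {
  g <- as_genotype(g, lnd$L)
  nb <- hamming_neighbors(g)
  w0 <- fitness(lnd, g)
  w <- fitness_many(lnd, nb)
  keep <- which(w > w0)
  tibble::tibble(
    locus = keep,
    genotype = if (length(keep)) gt_strings(nb[keep, , drop = FALSE]) else character(0),
    fitness = w[keep],
    s = w[keep] / w0 - 1
  )
}

#' SSWM fixation probabilities
#'
#' Under strong selection and weak mutation, the probability that the
#' beneficial mutation with selection coefficient `s_i` is the next to fix
#' is `s_i / sum(s)` (first-order in s; higher powers of the selection
#' coefficients are assumed negligible).
#'
#' @param s Positive selection coefficients of the available beneficial
#'   mutations.
#' @return Probabilities summing to 1.
#' @export
#' @examples
#' fixation_probabilities(c(0.1, 0.3))
fixation_probabilities <- function(s) {
  if (length(s) == 0L) {
    stop("no beneficial mutation available: genotype is a local optimum",
         call. = FALSE)
  }
  if (any(s <= 0)) stop("selection coefficients must be positive", call. = FALSE)
  s / sum(s)
}

#' Simulate one adaptive walk
#'
#' Starting from `start`, repeatedly moves to a strictly fitter mutational
#' neighbor — chosen with probability proportional to its selection
#' coefficient under `scheme = "sswm"`, or uniformly under
#' `scheme = "equal"` — until a local optimum is reached. Fitness increases
#' strictly at every step, so the walk always terminates within `2^L` steps.
#'
#' @param lnd A fitness landscape.
#' @param start Starting genotype.
#' @param scheme `"sswm"` or `"equal"`.
#' @param max_steps Safety guard; exceeding it signals a logic error.
#' @param seed Optional integer seed for an isolated, replayable walk.
#' @return A tibble of class `walk` with columns `position` (1-based),
#'   `genotype` (bitstring), `fitness`; attributes `scheme` and
#'   `genotype_matrix` (integer matrix of the visited genotypes).
#' @export
#' @examples
#' lnd <- nk_landscape(L = 6, K = 3, seed = 2)
#' run_walk(lnd, rep(0L, 6), seed = 7)
run_walk <- function(lnd, start, scheme = c("sswm", "equal"),
                     max_steps = 2^lnd$L, seed = NULL) {
  scheme <- match.arg(scheme)
  if (!is.null(seed)) {
    return(withr::with_seed(as.integer(seed),
                            run_walk(lnd, start, scheme, max_steps)))
  }
  g <- as_genotype(start, lnd$L)
  w <- fitness(lnd, g)
  path <- list(g)
  ws <- w
  steps <- 0L
  repeat {
    nb <- hamming_neighbors(g)
    wn <- fitness_many(lnd, nb)
    fitter <- which(wn > w)
    if (!length(fitter)) break
    if (steps >= max_steps) {
      stop("max_steps exceeded; this should be impossible on a finite landscape",
           call. = FALSE)
    }
    p <- if (scheme == "sswm") {
      fixation_probabilities(wn[fitter] / w - 1)
    } else {
      rep(1 / length(fitter), length(fitter))
    }
    pick <- fitter[sample.int(length(fitter), 1L, prob = p)]
    g <- nb[pick, ]
    w <- wn[pick]
    path[[length(path) + 1L]] <- g
    ws <- c(ws, w)
    steps <- steps + 1L
  }
  G <- do.call(rbind, path)
  out <- tibble::tibble(
    position = seq_len(nrow(G)),
    genotype = gt_strings(G),
    fitness = ws
  )
  attr(out, "scheme") <- scheme
  attr(out, "genotype_matrix") <- G
  class(out) <- c("walk", class(out))
  out
}
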