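# Independent oracles used across tests. Each recomputes a quantity by a
# different route than the implementation under test.

# NK fitness recomputed from the raw tables by explicit per-locus lookup,
# product, and L-th root (the implementation goes through mean-log).
oracle_nk_fitness <- function(lnd, g) {
  contribs <- vapply(seq_len(lnd$L), function(i) {
    state <- c(g[i], g[lnd$neighborhoods[[i]]])
    idx <- 1L
    for (b in seq_along(state)) idx <- idx + state[b] * 2L^(b - 1L)
    lnd$contributions[[i]][idx]
  }, numeric(1))
  prod(contribs)^(1 / lnd$L)
}

# Definitional sign-epistasis test: a mutation at one focal locus changes
# the direction of the fitness effect of a mutation at the other.
# Vectorized over quadruples in walk labelling (ab, Ab, aB, AB).
oracle_sign_epistasis <- function(w_ab, w_Ab, w_aB, w_AB) {
  eff1_bg_b <- w_Ab - w_ab   # locus-1 effect on background b
  eff1_bg_B <- w_AB - w_aB   # locus-1 effect on background B
  eff2_bg_a <- w_aB - w_ab   # locus-2 effect on background a
  eff2_bg_A <- w_AB - w_Ab   # locus-2 effect on background A
  (sign(eff1_bg_b) != sign(eff1_bg_B)) | (sign(eff2_bg_a) != sign(eff2_bg_A))
}

# Random walk-convention fitness quadruples: three of four i.i.d. uniforms
# sorted into the chain ab < Ab < AB, the fourth left free as aB.
random_walk_quadruples <- function(n) {
  w <- matrix(runif(4 * n, 0.5, 1.5), ncol = 4)
  chain <- t(apply(w[, 1:3, drop = FALSE], 1, sort))
  list(w_ab = chain[, 1], w_Ab = chain[, 2], w_AB = chain[, 3], w_aB = w[, 4])
}

# Orient an enumerated (canonical-corner) quadruple into the walk
# convention where possible: base at the minimum corner, its opposite as
# the double mutant. Returns walk-labelled fitnesses (rows where no
# increasing chain exists are flagged).
orient_enumerated <- function(q) {
  W <- cbind(q$w00, q$w10, q$w01, q$w11)
  opp <- c(4L, 3L, 2L, 1L)
  base <- max.col(-W, ties.method = "first")
  n <- nrow(W)
  ab <- W[cbind(seq_len(n), base)]
  AB <- W[cbind(seq_len(n), opp[base])]
  s1 <- W[cbind(seq_len(n), ifelse(base %in% c(1L, 4L), 2L, 1L))]
  s2 <- W[cbind(seq_len(n), ifelse(base %in% c(1L, 4L), 3L, 4L))]
  # choose as Ab a single mutant strictly inside (ab, AB); aB is the other
  use1 <- ab < s1 & s1 < AB
  use2 <- ab < s2 & s2 < AB
  Ab <- ifelse(use1, s1, s2)
  aB <- ifelse(use1, s2, s1)
  list(w_ab = ab, w_Ab = Ab, w_AB = AB, w_aB = aB, orientable = use1 | use2)
}
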