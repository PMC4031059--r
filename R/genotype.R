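# Genotypes are plain integer vectors of 0/1 of length L (0 = ancestral,
# 1 = derived allele). Locus indices are 1-based in R code; serialized
# bitstrings are written most-significant locus first ("010" = locus 2 derived).

#' Validate a genotype vector
#'
#' @param g Integer or numeric vector of 0/1 alleles.
#' @param L Optional expected locus count.
#' @return The genotype as an integer vector, invisibly validated.
#' @export
#' @examples
#' as_genotype(c(0, 1, 0))
as_genotype <- function(g, L = NULL) {
  g <- as.integer(g)
  if (!is.null(L) && length(g) != L) {
    stop("genotype has length ", length(g), ", expected L = ", L, call. = FALSE)
  }
  if (length(g) == 0L || !all(g %in% c(0L, 1L))) {
    stop("a genotype must be a non-empty vector of 0/1 alleles", call. = FALSE)
  }
  g
}

#' Convert between genotypes and bitstrings
#'
#' Bitstrings are written most-significant locus first, so locus 1 is the
#' leftmost character.
#'
#' @param g A genotype (integer 0/1 vector).
#' @return `gt_string()` returns a character scalar; `gt_parse()` the
#'   integer vector.
#' @export
#' @examples
#' gt_string(c(0, 1, 0))
#' gt_parse("010")
gt_string <- function(g) {
  paste(as.integer(g), collapse = "")
}

#' @rdname gt_string
#' @param s A bitstring such as `"0101"`.
#' @export
gt_parse <- function(s) {
  g <- as.integer(strsplit(s, "", fixed = TRUE)[[1]])
  as_genotype(g)
}

# Row-wise bitstrings for a 0/1 matrix, vectorized.
gt_strings <- function(G) {
  apply(G, 1L, paste, collapse = "")
}

#' Hamming distance between two genotypes
#'
#' @param a,b Genotypes of equal length.
#' @return Integer count of differing loci.
#' @export
hamming_distance <- function(a, b) {
  a <- as_genotype(a)
  b <- as_genotype(b, length(a))
  sum(a != b)
}

#' All single-mutation neighbors of a genotype
#'
#' Returns the L genotypes at Hamming distance 1, one per flipped locus,
#' ordered by locus index.
#'
#' @param g A genotype.
#' @return An integer matrix with L rows; row i is `g` with locus i flipped.
#' @export
#' @examples
#' hamming_neighbors(c(0, 0))
hamming_neighbors <- function(g) {
  g <- as_genotype(g)
  L <- length(g)
  M <- matrix(g, nrow = L, ncol = L, byrow = TRUE)
  diag(M) <- 1L - g
  M
}

#' Complete a walk triple into a quadruple
#'
#' Given three consecutive genotypes of an adaptive walk (`ab`, `Ab`, `AB`,
#' each one mutation apart and flipping two distinct loci in total), returns
#' the fourth genotype `aB` of the quadruple, i.e. the allele-wise XOR
#' `ab ^ Ab ^ AB`. The four genotypes then satisfy the two-locus closure:
#' `ab` and `AB` differ at exactly the two focal loci, and `Ab`, `aB` each
#' carry one of them.
#'
#' @param ab,Ab,AB Genotypes; `Ab` one flip from `ab`, `AB` one further flip
#'   at a different locus.
#' @return The genotype `aB`.
#' @export
#' @examples
#' complement_genotype(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
complement_genotype <- function(ab, Ab, AB) {
  ab <- as_genotype(ab)
  Ab <- as_genotype(Ab, length(ab))
  AB <- as_genotype(AB, length(ab))
  i <- which(ab != Ab)
  j <- which(Ab != AB)
  if (length(i) != 1L || length(j) != 1L) {
    stop("walk triple must advance by exactly one mutation per step", call. = FALSE)
  }
  if (i == j) {
    stop("walk triple flips the same locus twice; not a valid quadruple", call. = FALSE)
  }
  xor_genotypes(xor_genotypes(ab, Ab), AB)
}

xor_genotypes <- function(a, b) {
  as.integer((a + b) %% 2L)
}

# All 2^L genotypes as a 0/1 matrix; row r encodes integer r - 1 with locus 1
# as the most significant bit, matching the bitstring serialization and the
# indexing of full fitness tables.
all_genotypes <- function(L) {
  if (L > 22) stop("refusing to enumerate 2^", L, " genotypes", call. = FALSE)
  n <- 2L^L
  idx <- 0:(n - 1)
  G <- matrix(0L, nrow = n, ncol = L)
  for (l in seq_len(L)) {
    G[, l] <- as.integer(idx %/% 2^(L - l) %% 2)
  }
  G
}

# 1-based index of each genotype row into a full fitness table.
genotype_index <- function(G) {
  L <- ncol(G)
  as.integer(G %*% 2^((L - 1):0)) + 1L
}
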