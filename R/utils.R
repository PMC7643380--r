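#' Derive reproducible child seeds from a master seed
#'
#' One master seed fans out into independent substreams (per subject, per
#' null network, per optimization rep), so any single unit of the pipeline
#' can be re-run in isolation and reproduce its result bit-for-bit.
#'
#' @param base_seed Integer master seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(base_seed, n) {
  stopifnot(n >= 1)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(base_seed))
  out <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  out
}

#' Normalized mutual information between two partitions
#'
#' Symmetric-normalized NMI, `2 I(X;Y) / (H(X) + H(Y))`, used to score
#' recovery of planted community structure. Two identical labelings (up to
#' renaming) score 1; independent labelings score near 0. If both
#' partitions are single-community (zero entropy) they are identical and
#' the score is 1.
#'
#' @param a,b Integer vectors or matrices of community labels (multilayer
#'   partitions are flattened).
#' @return NMI in `[0, 1]`.
#' @export
partition_nmi <- function(a, b) {
  a <- as.vector(as.matrix(a))
  b <- as.vector(as.matrix(b))
  stopifnot(length(a) == length(b))
  n <- length(a)
  tab <- table(a, b)
  pj <- rowSums(tab) / n
  pk <- colSums(tab) / n
  pjk <- tab / n
  hx <- -sum(pj[pj > 0] * log(pj[pj > 0]))
  hy <- -sum(pk[pk > 0] * log(pk[pk > 0]))
  if (hx == 0 && hy == 0) return(1)
  nz <- pjk > 0
  mi <- sum(pjk[nz] * log(pjk[nz] / outer(pj, pk)[nz]))
  2 * mi / (hx + hy)
}
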