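#' Dirichlet-Multinomial probability mass function
#'
#' Log (or raw) probability of allele count vectors under the compound
#' Dirichlet-Multinomial distribution, the model used for overdispersed
#' sequencing-error counts. For a count vector \eqn{x} with total
#' \eqn{n = \sum_k x_k} and hyperparameter \eqn{\alpha} with
#' \eqn{A = \sum_k \alpha_k},
#' \deqn{\log P(x \mid \alpha) = \log\frac{n!}{\prod_k x_k!}
#'   + \log\Gamma(A) - \log\Gamma(n + A)
#'   + \sum_k \left[\log\Gamma(x_k + \alpha_k) - \log\Gamma(\alpha_k)\right].}
#'
#' @param x A non-negative count vector of length 4 (A, C, G, T order), or a
#'   matrix with one count vector per row.
#' @param alpha Strictly positive hyperparameter vector, same length as a row
#'   of `x`.
#' @param log Return log probabilities (default) or raw probabilities.
#' @return Numeric vector of (log) probabilities, one per row of `x`.
#' @examples
#' ddirmult(c(1, 0, 0, 0), c(1, 1, 1, 1))  # log(1/4)
#' @export
ddirmult <- function(x, alpha, log = TRUE) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (any(!is.finite(alpha)) || any(alpha <= 0))
    stop("'alpha' must be finite and strictly positive componentwise")
  if (length(alpha) != ncol(x))
    stop("'alpha' must have one component per count column")
  if (any(!is.finite(x)) || any(x < 0))
    stop("counts must be finite and non-negative")
  n <- rowSums(x)
  A <- sum(alpha)
  ll <- lgamma(n + 1) - rowSums(lgamma(x + 1)) +
    lgamma(A) - lgamma(n + A) +
    rowSums(lgamma(sweep(x, 2L, alpha, "+"))) - sum(lgamma(alpha))
  if (log) ll else exp(ll)
}

#' Draw Dirichlet-Multinomial count vectors
#'
#' Samples `n` count vectors: a base-composition probability vector is drawn
#' from Dirichlet(`alpha`), then counts from a multinomial with the given
#' total. Used by the synthetic-data generators and the `simulate()` method of
#' fitted null models.
#'
#' @param n Number of count vectors to draw.
#' @param size Multinomial total(s); recycled to length `n`.
#' @param alpha Strictly positive Dirichlet hyperparameter vector.
#' @return Integer matrix with `n` rows and `length(alpha)` columns.
#' @export
rdirmult <- function(n, size, alpha) {
  if (any(!is.finite(alpha)) || any(alpha <= 0))
    stop("'alpha' must be finite and strictly positive componentwise")
  k <- length(alpha)
  size <- rep_len(as.integer(size), n)
  if (any(size < 0)) stop("'size' must be non-negative")
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  p <- g / rowSums(g)
  out <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    if (size[i] > 0L) out[i, ] <- as.integer(rmultinom(1L, size[i], p[i, ]))
  }
  colnames(out) <- if (k == 4L) BASES else NULL
  out
}
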