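## Dirichlet-Multinomial null model of sequencing error, fitted per locus from
## control samples. Optimization is Newton-Raphson on theta = log(alpha)
## (unconstrained), with step halving to guarantee likelihood ascent and a
## digamma fixed-point fallback if the Newton step goes non-finite.

.dm_loglik <- function(alpha, x) sum(ddirmult(x, alpha))

.dm_grad <- function(alpha, x, n) {
  A <- sum(alpha)
  S <- nrow(x)
  colSums(digamma(sweep(x, 2L, alpha, "+"))) - S * digamma(alpha) +
    S * digamma(A) - sum(digamma(n + A))
}

.dm_hess <- function(alpha, x, n) {
  A <- sum(alpha)
  S <- nrow(x)
  off <- S * trigamma(A) - sum(trigamma(n + A))
  d <- colSums(trigamma(sweep(x, 2L, alpha, "+"))) - S * trigamma(alpha)
  H <- matrix(off, 4L, 4L)
  diag(H) <- diag(H) + d
  H
}

## moment-matching initializer: mean proportions scaled by a concentration
## solved from the overdispersion of per-sample proportions, floored at 1
.dm_init <- function(x, n) {
  p <- x / n
  pbar <- colMeans(p)
  v <- apply(p, 2L, var)
  nbar <- mean(n)
  binom_v <- pbar * (1 - pbar) / nbar
  ok <- is.finite(v) & v > 0 & binom_v > 0
  if (any(ok)) {
    r <- v[ok] / binom_v[ok]          # (nbar + A) / (1 + A)
    a_hat <- ifelse(r > 1, (nbar - r) / (r - 1), 1e6)
    A0 <- median(pmin(pmax(a_hat, 1), 1e6))
  } else {
    A0 <- 1e4
  }
  pmax(pbar, 1e-10) * max(A0, 1)
}

## one sweep of the digamma fixed-point ascent (used as fallback)
.dm_fixed_point <- function(alpha, x, n) {
  A <- sum(alpha)
  S <- nrow(x)
  num <- colSums(digamma(sweep(x, 2L, alpha, "+"))) - S * digamma(alpha)
  den <- sum(digamma(n + A)) - S * digamma(A)
  alpha * pmax(num, 1e-12) / max(den, 1e-12)
}

#' Fit the per-locus Dirichlet-Multinomial sequencing-error null
#'
#' Estimates the hyperparameter \eqn{\alpha} of a Dirichlet-Multinomial
#' distribution from the allele counts observed in control samples at one
#' locus, by maximising the joint log-likelihood with Newton-Raphson in
#' \eqn{\log\alpha} coordinates. Add-one smoothing (every allele count of
#' every control incremented by `smoothing`) is applied before fitting, so
#' every allele has positive observed mass and the maximum-likelihood
#' \eqn{\alpha} is finite even when an allele is never sequenced.
#'
#' Newton steps are halved whenever they would decrease the log-likelihood
#' (up to floating-point noise in the summed likelihood); if a step goes
#' non-finite the fit falls back to the digamma fixed-point ascent for that
#' iteration (recorded in `method`). Convergence is declared when the
#' gradient max-norm in \eqn{\log\alpha} coordinates drops below `tol`.
#'
#' The Dirichlet-Multinomial family contains the plain multinomial as its
#' \eqn{\sum\alpha \to \infty} boundary. When the (smoothed) control counts
#' show no overdispersion the likelihood is monotone in the concentration and
#' the MLE lies on that boundary, where no finite gradient tolerance can be
#' met. The fit detects this (concentration exceeding 1e8), stops at an
#' effectively-multinomial \eqn{\alpha}, and reports `converged = TRUE` with
#' `boundary = TRUE`: the model is usable (it is the multinomial limit), and
#' the condition is diagnosable.
#'
#' @param counts Control allele counts at one locus: a matrix with one row per
#'   control sample and columns A, C, G, T, or a count-table data.frame slice
#'   with `count_A`..`count_T` columns. At least two control samples are
#'   required.
#' @param smoothing Pseudocount added to every allele of every control sample
#'   before fitting (default 1, i.e. add-one smoothing).
#' @param tol Convergence tolerance on the gradient max-norm (default 1e-8).
#' @param max_iter Maximum Newton iterations (default 200).
#' @return An object of class `dm_null` with components `alpha` (named
#'   positive 4-vector), `concentration` (`sum(alpha)`), `loglik`,
#'   `n_controls`, `converged`, `boundary`, `iterations`, `gradient_norm`,
#'   `method`, and `trace` (the log-likelihood trajectory, non-decreasing up
#'   to floating-point noise).
#' @seealso [fit_null_all()] to fit every locus of a count table,
#'   [log_bayes_factor()] for scoring case samples against the fit.
#' @examples
#' set.seed(1)
#' x <- rdirmult(50, 2000, c(3000, 1, 1, 1))
#' fit <- fit_null(x)
#' coef(fit)
#' @export
fit_null <- function(counts, smoothing = 1, tol = 1e-8, max_iter = 200L) {
  x <- .count_matrix(counts)
  if (nrow(x) < 2L)
    stop("at least two control samples are required to fit the null")
  if (smoothing < 0) stop("'smoothing' must be non-negative")
  x <- x + smoothing
  if (any(rowSums(x) <= 0))
    stop("every smoothed control observation must have positive depth")
  n <- rowSums(x)

  alpha <- .dm_init(x, n)
  theta <- log(alpha)
  ll <- .dm_loglik(alpha, x)
  trace <- ll
  method <- "newton"
  converged <- FALSE
  boundary <- FALSE
  gnorm <- Inf
  it <- 0L
  A_BOUNDARY <- 1e8  # concentration past which the fit is multinomial in all but name

  while (it < max_iter) {
    it <- it + 1L
    alpha <- exp(theta)
    g_alpha <- .dm_grad(alpha, x, n)
    g <- alpha * g_alpha
    gnorm <- max(abs(g))
    if (gnorm < tol) {
      converged <- TRUE
      it <- it - 1L
      break
    }
    if (sum(alpha) > A_BOUNDARY) {
      ## likelihood monotone in the concentration: multinomial-limit MLE
      converged <- TRUE
      boundary <- TRUE
      it <- it - 1L
      break
    }
    H <- .dm_hess(alpha, x, n)
    Ht <- (alpha %o% alpha) * H
    diag(Ht) <- diag(Ht) + g
    step <- tryCatch(solve(Ht, g), error = function(e) NULL)
    ## the summed log-likelihood carries O(|ll|*eps) cancellation noise; a
    ## small FULL Newton step may gain less than that noise near the optimum
    ## (quadratic convergence) and is accepted at noise-equality; damped
    ## steps must strictly ascend so the iteration cannot drift
    ll_tol <- 1e-9 * (1 + abs(ll))
    theta_new <- NULL
    ll_new <- -Inf
    if (!is.null(step) && all(is.finite(step))) {
      t_step <- 1
      while (t_step >= 1e-10) {
        cand <- theta - t_step * step
        ll_c <- .dm_loglik(exp(cand), x)
        ok <- is.finite(ll_c) &&
          (ll_c > ll + ll_tol ||
             (t_step == 1 && max(abs(step)) < 0.1 && ll_c >= ll - ll_tol))
        if (ok) {
          theta_new <- cand
          ll_new <- ll_c
          break
        }
        t_step <- t_step / 2
      }
    }
    if (is.null(theta_new)) {
      ## Newton gave no ascent (unusable or indefinite-Hessian direction).
      ## Fall back to the best of: one digamma fixed-point sweep, and
      ## Levenberg-damped steps over a damping ladder (which limit to plain
      ## gradient ascent as the damping grows).
      afp <- .dm_fixed_point(alpha, x, n)
      ll_fp <- .dm_loglik(afp, x)
      if (is.finite(ll_fp) && ll_fp > ll + ll_tol) {
        theta_new <- log(afp)
        ll_new <- ll_fp
        method <- "newton+fixed-point"
      }
      scale <- max(1e-8, max(abs(diag(Ht))))
      for (lam in scale * 10^seq(-4, 8)) {
        Hd <- Ht
        diag(Hd) <- diag(Hd) - lam
        stepd <- tryCatch(solve(Hd, g), error = function(e) NULL)
        if (is.null(stepd) || any(!is.finite(stepd))) next
        cand <- theta - stepd
        ll_c <- .dm_loglik(exp(cand), x)
        if (is.finite(ll_c) && ll_c > ll + ll_tol && ll_c > ll_new) {
          theta_new <- cand
          ll_new <- ll_c
          method <- "newton+damped"
        }
      }
    }
    ## boundary acceleration: when the likelihood still ascends along the
    ## concentration ray (alpha -> 10 alpha) the optimum may be the
    ## multinomial limit, where Newton steps shrink against the vanishing
    ## curvature; take the ray step whenever it beats the other candidates
    ll_jump <- .dm_loglik(exp(theta + log(10)), x)
    if (is.finite(ll_jump) && ll_jump > ll + ll_tol && ll_jump > ll_new) {
      theta_new <- theta + log(10)
      ll_new <- ll_jump
    }
    if (is.null(theta_new)) {
      ## no ascent direction remains at this numerical resolution
      break
    }
    theta <- theta_new
    ll <- ll_new
    trace <- c(trace, ll)
  }

  alpha <- setNames(exp(theta), BASES)
  structure(
    list(
      alpha = alpha,
      concentration = sum(alpha),
      loglik = ll,
      n_controls = nrow(x),
      converged = converged,
      boundary = boundary,
      iterations = it,
      gradient_norm = gnorm,
      method = method,
      smoothing = smoothing,
      mean_depth = mean(n) - 4 * smoothing,
      trace = trace
    ),
    class = "dm_null"
  )
}

#' @export
print.dm_null <- function(x, ...) {
  cat("Dirichlet-Multinomial sequencing-error null\n")
  cat(sprintf("  controls: %d   mean depth: %.0f\n", x$n_controls, x$mean_depth))
  cat("  alpha:\n")
  print(round(x$alpha, 4))
  cat(sprintf("  concentration: %.2f   logLik: %.3f\n", x$concentration, x$loglik))
  state <- if (x$boundary) "converged (multinomial boundary)"
           else if (x$converged) "converged" else "NOT converged"
  cat(sprintf("  %s in %d iterations (gradient max-norm %.2e)\n",
              state, x$iterations, x$gradient_norm))
  invisible(x)
}

#' @export
coef.dm_null <- function(object, ...) object$alpha

#' @export
logLik.dm_null <- function(object, ...) {
  structure(object$loglik, df = 4L, nobs = object$n_controls, class = "logLik")
}

#' @export
summary.dm_null <- function(object, ...) {
  out <- list(
    alpha = object$alpha,
    proportions = object$alpha / object$concentration,
    concentration = object$concentration,
    loglik = object$loglik,
    n_controls = object$n_controls,
    converged = object$converged,
    iterations = object$iterations,
    method = object$method
  )
  class(out) <- "summary.dm_null"
  out
}

#' @export
print.summary.dm_null <- function(x, ...) {
  cat("Dirichlet-Multinomial null summary\n")
  m <- rbind(alpha = x$alpha, proportion = x$proportions)
  print(round(m, 6))
  cat(sprintf("concentration %.2f, logLik %.3f, %d controls, %s (%d iter, %s)\n",
              x$concentration, x$loglik, x$n_controls,
              if (x$converged) "converged" else "not converged",
              x$iterations, x$method))
  invisible(x)
}

#' Simulate allele counts from a fitted null
#'
#' Draws Dirichlet-Multinomial count vectors from the fitted error model, at a
#' fixed or per-draw depth.
#'
#' @param object A `dm_null` fit.
#' @param nsim Number of count vectors.
#' @param seed Optional integer seed.
#' @param depth Multinomial total(s); defaults to the mean control depth.
#' @param ... Unused.
#' @return Integer matrix `nsim` x 4.
#' @export
simulate.dm_null <- function(object, nsim = 1, seed = NULL,
                             depth = round(object$mean_depth), ...) {
  if (!is.null(seed)) set.seed(seed)
  rdirmult(nsim, depth, object$alpha)
}

#' Fit the sequencing-error null at every locus of a control count table
#'
#' Splits a long-format count table by locus and fits [fit_null()] at each.
#' Loci where the fit does not converge are flagged, not dropped; loci listed
#' in `loci` but absent from the controls are reported in the `skipped`
#' attribute rather than silently ignored.
#'
#' @param counts Control count table: data.frame with columns `sample_id`,
#'   `chrom`, `pos`, `ref`, `count_A`..`count_T`.
#' @param loci Optional data.frame (`chrom`, `pos`) of target loci the fit
#'   must cover.
#' @param ... Passed to [fit_null()] (`smoothing`, `tol`, `max_iter`).
#' @return A `dm_null_set`: named list of `dm_null` fits keyed `chrom:pos`,
#'   with a `loci` attribute (chrom, pos, ref) and a `skipped` attribute.
#'   `as.data.frame()` gives the flat null-model table.
#' @export
fit_null_all <- function(counts, loci = NULL, ...) {
  req <- c("sample_id", "chrom", "pos", "ref", paste0("count_", BASES))
  if (!is.data.frame(counts) || !all(req %in% names(counts)))
    stop("'counts' must be a count table with columns: ",
         paste(req, collapse = ", "))
  if (nrow(counts) == 0L) stop("empty control count table")
  key <- .locus_key(counts$chrom, counts$pos)
  skipped <- character(0)
  if (!is.null(loci)) {
    want <- .locus_key(loci$chrom, loci$pos)
    skipped <- setdiff(want, unique(key))
  }
  idx <- split(seq_len(nrow(counts)), key)
  fits <- lapply(idx, function(i) {
    f <- fit_null(counts[i, , drop = FALSE], ...)
    f$chrom <- counts$chrom[i[1L]]
    f$pos <- counts$pos[i[1L]]
    f$ref <- counts$ref[i[1L]]
    f
  })
  first <- vapply(idx, `[`, 0L, 1L)
  ord <- order(counts$chrom[first], counts$pos[first])
  fits <- fits[ord]
  locus_df <- data.frame(
    chrom = vapply(fits, `[[`, "", "chrom"),
    pos = vapply(fits, function(f) as.integer(f$pos), 0L),
    ref = vapply(fits, `[[`, "", "ref"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(fits, class = "dm_null_set", loci = locus_df, skipped = skipped)
}

#' @export
print.dm_null_set <- function(x, ...) {
  conv <- vapply(x, `[[`, TRUE, "converged")
  cat(sprintf("dm_null_set: %d loci (%d converged, %d flagged)\n",
              length(x), sum(conv), sum(!conv)))
  sk <- attr(x, "skipped")
  if (length(sk)) cat("  skipped loci (absent from controls):",
                      paste(sk, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.dm_null_set <- function(x, ...) {
  data.frame(
    chrom = vapply(x, `[[`, "", "chrom"),
    pos = vapply(x, function(f) as.integer(f$pos), 0L),
    ref = vapply(x, `[[`, "", "ref"),
    alpha_A = vapply(x, function(f) f$alpha[["A"]], 0),
    alpha_C = vapply(x, function(f) f$alpha[["C"]], 0),
    alpha_G = vapply(x, function(f) f$alpha[["G"]], 0),
    alpha_T = vapply(x, function(f) f$alpha[["T"]], 0),
    concentration = vapply(x, `[[`, 0, "concentration"),
    loglik = vapply(x, `[[`, 0, "loglik"),
    converged = vapply(x, `[[`, TRUE, "converged"),
    boundary = vapply(x, `[[`, TRUE, "boundary"),
    iterations = vapply(x, function(f) as.integer(f$iterations), 0L),
    n_controls = vapply(x, function(f) as.integer(f$n_controls), 0L),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' @export
`[.dm_null_set` <- function(x, i) {
  out <- unclass(x)[i]
  structure(out, class = "dm_null_set",
            loci = attr(x, "loci")[i, , drop = FALSE],
            skipped = attr(x, "skipped"))
}
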