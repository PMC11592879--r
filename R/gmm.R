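#' Gaussian-mixture tissue segmentation
#'
#' Fits a K-component univariate Gaussian mixture to voxel intensities by
#' expectation-maximization and returns per-voxel posterior probability
#' maps — the intensity-only core of unified tissue segmentation
#' (CSF / gray matter / white matter for K = 3). Components are reported
#' sorted by mean. Means are initialized at evenly spaced intensity
#' quantiles (deterministic); if a component's responsibility mass
#' collapses it is re-seeded once at a random data point and pruned if it
#' collapses again. Hitting the iteration cap without meeting the
#' log-likelihood tolerance yields a warning and the best iterate.
#'
#' @param volume Numeric array (any shape) of finite intensities.
#' @param K Number of tissue classes (>= 1).
#' @param max_iter EM iteration cap (default 200).
#' @param tol Convergence tolerance on the relative log-likelihood change
#'   (default 1e-8).
#' @return A `gmm_fit`: list with `means`, `sds`, `weights` (sorted by
#'   mean), `posterior` (list of K arrays shaped like `volume`, summing to
#'   1 voxelwise), `labels` (argmax-posterior array), `loglik`,
#'   `iterations`, `converged`.
#' @export
#' @examples
#' tv <- gen_tissue_volume(synth_tissue_config(grid_shape = c(8, 8, 8)))
#' fit <- gmm_segment(tv$volume, K = 3)
#' fit$means
gmm_segment <- function(volume, K, max_iter = 200, tol = 1e-8) {
  if (K < 1) stop("K must be >= 1")
  x <- as.numeric(volume)
  if (!all(is.finite(x))) stop("intensities must be finite")
  n <- length(x)
  shp <- if (is.null(dim(volume))) length(x) else dim(volume)

  if (K == 1) {
    mu <- mean(x); s <- stats::sd(x)
    post <- list(array(1, shp))
    return(structure(list(means = mu, sds = s, weights = 1,
                          posterior = post, labels = array(1L, shp),
                          loglik = sum(dnorm(x, mu, s, log = TRUE)),
                          iterations = 0L, converged = TRUE),
                     class = "gmm_fit"))
  }

  # deterministic init: evenly spaced quantiles
  mu <- as.numeric(stats::quantile(x, probs = (seq_len(K) - 0.5) / K))
  s <- rep(stats::sd(x) / K, K)
  w <- rep(1 / K, K)
  s[s <= 0] <- .Machine$double.eps

  ll_old <- -Inf; converged <- FALSE; it <- 0L
  reseeded <- rep(FALSE, K)
  alive <- rep(TRUE, K)
  resp <- NULL
  while (it < max_iter) {
    it <- it + 1L
    # E step (log-sum-exp for stability)
    lp <- vapply(seq_len(K), function(k) {
      if (!alive[k]) return(rep(-Inf, n))
      log(w[k]) + dnorm(x, mu[k], s[k], log = TRUE)
    }, numeric(n))
    m <- apply(lp, 1, max)
    lse <- m + log(rowSums(exp(lp - m)))
    resp <- exp(lp - lse)
    ll <- sum(lse)

    # M step
    nk <- colSums(resp)
    for (k in seq_len(K)) {
      if (!alive[k]) next
      if (nk[k] < 1e-8) {
        if (!reseeded[k]) {        # re-seed once at a random data point
          reseeded[k] <- TRUE
          mu[k] <- x[sample.int(n, 1)]
          s[k] <- stats::sd(x) / K
          w[k] <- 1 / K
          next
        }
        alive[k] <- FALSE          # prune permanently empty component
        w[k] <- 0
        next
      }
      mu[k] <- sum(resp[, k] * x) / nk[k]
      s[k] <- sqrt(sum(resp[, k] * (x - mu[k])^2) / nk[k])
      if (!is.finite(s[k]) || s[k] < 1e-12) s[k] <- 1e-12
      w[k] <- nk[k] / n
    }
    w[alive] <- w[alive] / sum(w[alive])

    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  if (!converged) warning("EM hit the iteration cap (", max_iter,
                          ") before converging; returning best iterate")

  keep <- which(alive)
  ord <- keep[order(mu[keep])]
  post <- lapply(ord, function(k) array(resp[, k], shp))
  # renormalize over surviving components
  tot <- Reduce(`+`, post)
  post <- lapply(post, function(p) p / tot)
  lab_flat <- max.col(do.call(cbind, lapply(post, as.numeric)))
  structure(list(means = mu[ord], sds = s[ord], weights = w[ord] / sum(w[ord]),
                 posterior = post, labels = array(lab_flat, shp),
                 loglik = ll_old, iterations = it, converged = converged),
            class = "gmm_fit")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("<gmm_fit> %d component(s), loglik %.2f (%d iterations%s)\n",
              length(x$means), x$loglik, x$iterations,
              if (x$converged) "" else ", not converged"))
  print(data.frame(mean = x$means, sd = x$sds, weight = x$weights),
        row.names = FALSE)
  invisible(x)
}
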