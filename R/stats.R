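# Nonparametric statistics.: cluster-mass permutation tests, FDR, signed rank.

#' Cluster-mass permutation test on paired maps
#'
#' Family-wise-error-controlled comparison of two paired map-shaped
#' conditions (sessions x depth x time, or x frequency). A pixelwise paired
#' statistic (signed-rank z by default, optionally paired t) is thresholded
#' at the two-sided cluster-forming level; supra-threshold pixels form
#' 4-connected clusters whose mass is the sum of |statistic|. The null is
#' generated by random per-session sign flips of the paired differences
#' (condition exchange); each cluster's p-value is the fraction of
#' permutation maximum masses at least as large as its mass. When
#' `2^n_sessions <= 4096` all sign patterns are enumerated and the test is
#' exact.
#'
#' @param maps_a,maps_b numeric arrays, sessions x dim1 x dim2.
#' @param alpha cluster significance level (default 0.05).
#' @param n_perm random permutations when enumeration is infeasible
#'   (default 1000; values below 100 are refused).
#' @param statistic `"signed_rank"` (default) or `"t"`.
#' @param cluster_p two-sided pixelwise cluster-forming p (default 0.05).
#' @param seed RNG seed for random permutations.
#' @return object of class `cluster_test`: `clusters` tibble (id, mass,
#'   p_value, n_pixels), `labels` matrix, `mask` (significant at `alpha`),
#'   `stat` map, `threshold`, `n_permutations`, `exact`.
#' @export
cluster_mass_test <- function(maps_a, maps_b, alpha = 0.05, n_perm = 1000,
                              statistic = c("signed_rank", "t"),
                              cluster_p = 0.05, seed = 1) {
  statistic <- match.arg(statistic)
  if (!identical(dim(maps_a), dim(maps_b)) || length(dim(maps_a)) != 3L) {
    abort("maps must be paired sessions x dim1 x dim2 arrays")
  }
  n <- dim(maps_a)[1L]
  d1 <- dim(maps_a)[2L]
  d2 <- dim(maps_a)[3L]
  if (n < 2L) abort("need at least 2 sessions")
  if (n < 6L) warn("fewer than 6 sessions: permutation resolution is coarse")
  if (n_perm < 100L) abort("n_perm below 100 is refused")

  D <- matrix(maps_a - maps_b, nrow = n)   # sessions x pixels

  exact <- 2^n <= 4096
  S <- if (exact) {
    # all sign patterns, identity first
    grid <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    rbind(rep(1, n), grid[rowSums(grid == 1) != n, , drop = FALSE])
  } else {
    with_stream(seed, "cluster-perm", {
      rbind(rep(1, n),
            matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n_perm, n))
    })
  }

  if (statistic == "signed_rank") {
    C <- apply(D, 2L, function(d) {
      out <- numeric(n)
      nz <- d != 0
      if (any(nz)) out[nz] <- sign(d[nz]) * rank(abs(d[nz]))
      out
    })
    denom <- sqrt(colSums(C^2))
    denom[denom == 0] <- Inf
    Z <- (S %*% C) / rep(denom, each = nrow(S))
    thresh <- stats::qnorm(1 - cluster_p / 2)
  } else {
    ss <- colSums(D^2)
    M <- (S %*% D) / n
    V <- (rep(ss, each = nrow(S)) - n * M^2) / (n - 1)
    V[V <= 0] <- Inf
    Z <- M / sqrt(V / n)
    thresh <- stats::qt(1 - cluster_p / 2, df = n - 1)
  }

  obs <- matrix(Z[1L, ], d1, d2)
  comp <- cluster_components_cpp(obs, thresh)
  null_max <- max_cluster_mass_batch_cpp(Z[-1L, , drop = FALSE], d1, d2, thresh)

  masses <- as.numeric(comp$masses)
  nperm_eff <- length(null_max)
  p_vals <- vapply(masses, function(m) {
    if (exact) mean(c(null_max, m) >= m) else
      (1 + sum(null_max >= m)) / (nperm_eff + 1)
  }, numeric(1))
  clusters <- tibble(id = seq_along(masses), mass = masses, p_value = p_vals,
                     n_pixels = vapply(seq_along(masses),
                                       function(k) sum(comp$labels == k),
                                       integer(1)))
  sig_ids <- clusters$id[clusters$p_value <= alpha]
  mask <- matrix(comp$labels %in% sig_ids, d1, d2)
  structure(list(clusters = clusters, labels = comp$labels, mask = mask,
                 stat = obs, threshold = thresh, alpha = alpha,
                 n_permutations = nperm_eff, exact = exact,
                 statistic = statistic),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> %s statistic, %d clusters, %d %s permutations\n",
              x$statistic, nrow(x$clusters), x$n_permutations,
              if (x$exact) "exhaustive" else "random"))
  sig <- x$clusters[x$clusters$p_value <= x$alpha, ]
  cat(sprintf("  %d significant at alpha = %g\n", nrow(sig), x$alpha))
  invisible(x)
}

#' @export
tidy.cluster_test <- function(x, ...) x$clusters

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR adjustment of a vector of p-values.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
fdr_bh <- function(p_values) {
  if (!is.numeric(p_values) ||
      any(!is.finite(p_values) | p_values < 0 | p_values > 1)) {
    abort("p-values must be finite and inside [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Two-sided paired Wilcoxon signed-rank p-value
#'
#' Exact by full sign-flip enumeration for small samples (n <= 12 after
#' dropping zero differences, ties handled by mid-ranks), so e.g.
#' all-positive differences at n = 12 give p = 2/2^12; larger samples use
#' the standard signed-rank test. All-zero differences return p = 1 by
#' convention.
#'
#' @param a,b paired numeric vectors, n >= 5.
#' @return two-sided p-value.
#' @export
paired_signed_rank <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must be paired")
  if (length(a) < 5L) abort("signed-rank comparison needs n >= 5")
  if (any(!is.finite(a)) || any(!is.finite(b))) abort("values must be finite")
  d <- a - b
  d <- d[d != 0]
  if (!length(d)) {
    inform("all paired differences are zero; returning p = 1")
    return(1)
  }
  n <- length(d)
  if (n <= 12L) {
    r <- rank(abs(d))
    w_obs <- sum(sign(d) * r)
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    w_null <- as.vector(signs %*% r)
    mean(abs(w_null) >= abs(w_obs))
  } else {
    suppressWarnings(wilcox.test(a, b, paired = TRUE)$p.value)
  }
}
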