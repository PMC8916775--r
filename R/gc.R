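# Pairwise spectral Granger causality (Geweke), band integration, net
# directionality, and the time-reversal (RGT) control.

#' Fit a bivariate VAR to multi-trial data
#'
#' Ordinary least squares over all trials jointly, after per-trial demeaning;
#' no intercept. The default model order of 50 corresponds to ~50 ms of
#' history at a ~1 kHz bin rate.
#'
#' @param x,y trials x time matrices (same shape); one stretch of analysis
#'   bins per trial (the pipeline uses 256 bins from 200 ms after onset).
#' @param order model order p (default 50).
#' @param fs_hz bin rate, Hz (default 1000), carried into the model for the
#'   frequency axis.
#' @return object of class `var_model`: `A` (2 x 2 x p coefficient array),
#'   `sigma` (2 x 2 innovation covariance), `order`, `fs_hz`,
#'   `n_obs_effective`, `spectral_radius`.
#' @export
fit_var_pair <- function(x, y, order = 50, fs_hz = 1000) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (is.vector(y)) y <- matrix(y, nrow = 1L)
  stopifnot(all(dim(x) == dim(y)))
  p <- as.integer(order)
  ntr <- nrow(x)
  nb <- ncol(x)
  if (nb <= p + 2L) abort("trials are shorter than the model order")
  n_eff <- ntr * (nb - p)
  n_par <- 2L * p
  if (n_eff * 2L < 10L * n_par * 2L) {
    warn(sprintf("only %d observations for %d parameters; VAR estimate may be unstable",
                 n_eff * 2L, n_par * 2L))
  }
  if (sd(as.vector(x)) == 0 || sd(as.vector(y)) == 0) {
    abort("zero-variance input: VAR fit is singular")
  }
  X <- matrix(0, n_eff, n_par)
  Y <- matrix(0, n_eff, 2L)
  row0 <- 0L
  for (tr in seq_len(ntr)) {
    z <- cbind(x[tr, ] - mean(x[tr, ]), y[tr, ] - mean(y[tr, ]))
    E <- stats::embed(z, p + 1L)          # [z_t, z_{t-1}, ..., z_{t-p}]
    idx <- row0 + seq_len(nb - p)
    Y[idx, ] <- E[, 1:2]
    X[idx, ] <- E[, -(1:2), drop = FALSE]
    row0 <- row0 + (nb - p)
  }
  qrX <- qr(X)
  if (qrX$rank < n_par) abort("singular VAR design matrix")
  B <- qr.coef(qrX, Y)                    # (2p) x 2
  resid <- Y - X %*% B
  sigma <- crossprod(resid) / (n_eff - n_par)
  A <- array(0, dim = c(2L, 2L, p))
  for (k in seq_len(p)) A[, , k] <- t(B[(2L * k - 1L):(2L * k), ])
  sr <- var_spectral_radius(A)
  if (sr >= 1) {
    abort(sprintf("fitted VAR is unstable (spectral radius %.4f >= 1)", sr))
  }
  structure(list(A = A, sigma = unname(sigma), order = p, fs_hz = fs_hz,
                 n_obs_effective = n_eff, spectral_radius = sr),
            class = "var_model")
}

var_spectral_radius <- function(A) {
  p <- dim(A)[3L]
  m <- 2L * p
  C <- matrix(0, m, m)
  for (k in seq_len(p)) C[1:2, (2L * k - 1L):(2L * k)] <- A[, , k]
  if (p > 1L) C[3:m, 1:(m - 2L)] <- diag(m - 2L)
  max(Mod(eigen(C, only.values = TRUE)$values))
}

#' @export
print.var_model <- function(x, ...) {
  cat(sprintf("<var_model> bivariate VAR(%d) @ %g Hz, %d effective obs, spectral radius %.3f\n",
              x$order, x$fs_hz, x$n_obs_effective, x$spectral_radius))
  invisible(x)
}

#' Geweke's frequency-domain Granger causality from a fitted VAR
#'
#' From the coefficient polynomial `A(f) = I - sum_k A_k exp(-2 pi i f k /
#' fs)` the transfer function `H(f) = A(f)^-1` and spectral matrix
#' `S(f) = H Sigma H*` are formed, and the directed measure is
#' `f_{y->x}(f) = ln S_xx / (|H_xx + (Sigma_xy/Sigma_xx) H_xy|^2 Sigma_xx)`,
#' the standard noise-covariance partialing. Computed via `log1p` of the
#' causal-to-intrinsic power ratio, so the result is non-negative by
#' construction.
#'
#' @param model a [fit_var_pair()] result (or any list with `A`, `sigma`,
#'   `fs_hz`).
#' @param freq_hz frequency grid; default: FFT bins of n = 1024 at `fs_hz`
#'   restricted to 1-100 Hz (aligned with the spectrogram grid).
#' @return object of class `gc_spectrum`: `freq_hz`, `fwd` (x -> y),
#'   `bwd` (y -> x), both in nats.
#' @export
geweke_spectral_gc <- function(model, freq_hz = NULL) {
  fs <- model$fs_hz
  freq_hz <- freq_hz %||% {
    f <- (0:512) * fs / 1024
    f[f >= 1 & f <= 100]
  }
  A <- model$A
  S <- model$sigma
  p <- dim(A)[3L]
  sxx <- S[1, 1]; syy <- S[2, 2]; sxy <- S[1, 2]
  s_yy_part <- syy - sxy^2 / sxx   # y-innovation variance given x
  s_xx_part <- sxx - sxy^2 / syy
  fwd <- bwd <- numeric(length(freq_hz))
  for (i in seq_along(freq_hz)) {
    w <- -2i * pi * freq_hz[i] / fs
    Af <- diag(2) + 0i
    for (k in seq_len(p)) Af <- Af - A[, , k] * exp(w * k)
    H <- tryCatch(solve(Af), error = function(e) NULL)
    if (is.null(H)) {
      fwd[i] <- NA_real_; bwd[i] <- NA_real_
      next
    }
    # y -> x: causal power |H_xy|^2 * partial y innovation vs intrinsic power
    h_xx_t <- H[1, 1] + (sxy / sxx) * H[1, 2]
    bwd[i] <- log1p(Mod(H[1, 2])^2 * s_yy_part / (Mod(h_xx_t)^2 * sxx))
    # x -> y
    h_yy_t <- H[2, 2] + (sxy / syy) * H[2, 1]
    fwd[i] <- log1p(Mod(H[2, 1])^2 * s_xx_part / (Mod(h_yy_t)^2 * syy))
  }
  structure(list(freq_hz = freq_hz, fwd = fwd, bwd = bwd),
            class = "gc_spectrum")
}

#' @export
print.gc_spectrum <- function(x, ...) {
  cat(sprintf("<gc_spectrum> %d frequencies %g-%g Hz; mean fwd %.4g, mean bwd %.4g nats\n",
              length(x$freq_hz), min(x$freq_hz), max(x$freq_hz),
              mean(x$fwd, na.rm = TRUE), mean(x$bwd, na.rm = TRUE)))
  invisible(x)
}

#' Tidy a GC spectrum
#' @param x a `gc_spectrum`.
#' @param ... unused.
#' @export
tidy.gc_spectrum <- function(x, ...) {
  tibble(freq_hz = rep(x$freq_hz, 2L),
         direction = rep(c("forward", "backward"), each = length(x$freq_hz)),
         gci = c(x$fwd, x$bwd))
}

#' Band-integrated and net Granger causality
#'
#' Integrates the GC index over a frequency band (as the mean over band
#' bins, which is invariant to the density of the frequency grid) and forms
#' the net index as forward minus backward.
#'
#' @param spec a [geweke_spectral_gc()] result.
#' @param band band corners, Hz.
#' @return list with `gci_fwd`, `gci_bwd`, `net`.
#' @export
band_net_gc <- function(spec, band) {
  stopifnot(inherits(spec, "gc_spectrum"))
  sel <- spec$freq_hz >= band[1] & spec$freq_hz <= band[2]
  if (!any(sel)) abort(sprintf("band %g-%g Hz is empty on this grid", band[1], band[2]))
  fwd <- mean(spec$fwd[sel], na.rm = TRUE)
  bwd <- mean(spec$bwd[sel], na.rm = TRUE)
  list(gci_fwd = fwd, gci_bwd = bwd, net = fwd - bwd)
}

band_net_from_trials <- function(x, y, band, order, fs_hz) {
  band_net_gc(geweke_spectral_gc(fit_var_pair(x, y, order, fs_hz)), band)$net
}

#' Time-reversal control for a Granger-causal connection (RGT)
#'
#' Genuine lagged interactions flip their dominant direction when every
#' trial is time-reversed, whereas instantaneously mixed common noise does
#' not: time reversal leaves lag-zero covariance untouched. The test
#' recomputes the band net GC on trial-wise reversed data and passes when
#' (i) the net sign flips and (ii) both net magnitudes exceed a floor.
#' The floor is a significance requirement: `z_crit` times the trial-
#' bootstrap standard error of the net index. The bootstrap resamples whole
#' trials with the x/y pairing intact, so it captures the sampling
#' variability that instantaneous common noise induces in the net index —
#' variability that a pairing-destroying shuffle null would miss.
#'
#' @param x,y trials x time matrices.
#' @param band band corners, Hz.
#' @param order VAR model order (default 50).
#' @param fs_hz bin rate, Hz.
#' @param n_boot trial-bootstrap replicates for the floor (default 19); set
#'   to 0 to use `floor_abs` alone.
#' @param z_crit multiplier on the bootstrap SE (default `qnorm(0.975)`).
#' @param floor_abs fixed magnitude floor (always applied; default 0).
#' @param seed seed for the bootstrap.
#' @return list: `pass`, `net`, `net_reversed`, `floor`.
#' @export
reverse_granger_test <- function(x, y, band, order = 50, fs_hz = 1000,
                                 n_boot = 19, z_crit = stats::qnorm(0.975),
                                 floor_abs = 0, seed = 1) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (is.vector(y)) y <- matrix(y, nrow = 1L)
  net <- band_net_from_trials(x, y, band, order, fs_hz)
  xr <- x[, rev(seq_len(ncol(x))), drop = FALSE]
  yr <- y[, rev(seq_len(ncol(y))), drop = FALSE]
  net_rev <- band_net_from_trials(xr, yr, band, order, fs_hz)
  floor_val <- floor_abs
  if (n_boot > 0L && nrow(x) > 2L) {
    boots <- with_stream(seed, "rgt-boot", {
      vapply(seq_len(n_boot), function(k) {
        idx <- sample.int(nrow(x), replace = TRUE)
        band_net_from_trials(x[idx, , drop = FALSE], y[idx, , drop = FALSE],
                             band, order, fs_hz)
      }, numeric(1))
    })
    floor_val <- max(floor_abs, z_crit * sd(boots))
  }
  pass <- is.finite(net) && is.finite(net_rev) &&
    sign(net) != sign(net_rev) &&
    abs(net) > floor_val && abs(net_rev) > floor_val
  list(pass = pass, net = net, net_reversed = net_rev, floor = floor_val)
}

#' Extract the GC analysis segment from an epoched signal
#'
#' @param epoched an [epoched_signal()].
#' @param channel channel index.
#' @param condition optional stimulus diameter filter.
#' @param start_ms segment start (default 200 ms after onset).
#' @param n_bins segment length in bins (default 256).
#' @return trials x n_bins matrix.
#' @export
gc_segment <- function(epoched, channel, condition = NULL, start_ms = 200,
                       n_bins = 256) {
  stopifnot(inherits(epoched, "epoched_signal"))
  i0 <- which(epoched$time_ms >= start_ms)[1]
  if (is.na(i0) || i0 + n_bins - 1L > length(epoched$time_ms)) {
    abort("epoch does not contain the requested GC segment")
  }
  trials <- if (is.null(condition)) seq_len(dim(epoched$data)[1L]) else
    which(epoched$condition == condition)
  epoched$data[trials, channel, i0:(i0 + n_bins - 1L), drop = TRUE] |>
    matrix(nrow = length(trials))
}

#' Granger-causality graph over all channel pairs and bands
#'
#' Fits a bivariate VAR per unordered channel pair on the sustained-response
#' segment, integrates the Geweke spectrum in each band, forms net GC and
#' runs the time-reversal control. Rows are emitted for both orderings of
#' each pair (net GC is antisymmetric by construction; the RGT status is a
#' property of the pair).
#'
#' @param epoched an [epoched_signal()] (normally kind `"LFPbp"`).
#' @param bands named list of band corners, default [classic_bands()].
#' @param depths optional depth map from [assign_depths()].
#' @param channels channels to include (default: usable ones).
#' @param condition optional stimulus diameter filter.
#' @param order,start_ms,n_bins see [fit_var_pair()] and [gc_segment()].
#' @param n_null trial-bootstrap replicates for the per-band reversal-test
#'   floor (see [reverse_granger_test()]); 0 disables the floor.
#' @param seed seed for the reversal-test bootstrap.
#' @return tibble of class `gc_graph`: source, target, band, gci_fwd,
#'   gci_bwd, net, rgt_pass (plus depths when given). Pairs whose VAR fit
#'   fails are recorded in the `failed_pairs` attribute.
#' @export
build_gc_graph <- function(epoched, bands = classic_bands(), depths = NULL,
                           channels = NULL, condition = NULL, order = 50,
                           start_ms = 200, n_bins = 256, n_null = 19,
                           seed = 1) {
  stopifnot(inherits(epoched, "epoched_signal"))
  channels <- channels %||% which(epoched$usable)
  if (length(channels) < 2L) abort("GC graph needs at least 2 usable channels")
  segs <- lapply(channels, gc_segment, epoched = epoched,
                 condition = condition, start_ms = start_ms, n_bins = n_bins)
  names(segs) <- as.character(channels)
  rows <- list()
  failed <- list()
  pairs <- utils::combn(channels, 2L)
  for (pi in seq_len(ncol(pairs))) {
    i <- pairs[1L, pi]; j <- pairs[2L, pi]
    xi <- segs[[as.character(i)]]; xj <- segs[[as.character(j)]]
    res <- tryCatch({
      spec <- geweke_spectral_gc(fit_var_pair(xi, xj, order, epoched$fs_hz))
      spec_rev <- geweke_spectral_gc(fit_var_pair(
        xi[, rev(seq_len(ncol(xi))), drop = FALSE],
        xj[, rev(seq_len(ncol(xj))), drop = FALSE], order, epoched$fs_hz))
      boots <- NULL
      if (n_null > 0L && nrow(xi) > 2L) {
        boots <- with_stream(seed + i * 131L + j, "gc-graph-boot", {
          lapply(seq_len(n_null), function(k) {
            idx <- sample.int(nrow(xi), replace = TRUE)
            geweke_spectral_gc(fit_var_pair(xi[idx, , drop = FALSE],
                                            xj[idx, , drop = FALSE],
                                            order, epoched$fs_hz))
          })
        })
      }
      purrr::imap_dfr(bands, function(band, bname) {
        bn <- band_net_gc(spec, band)
        bn_rev <- band_net_gc(spec_rev, band)
        floor_val <- 0
        if (!is.null(boots)) {
          boot_nets <- vapply(boots, function(s) band_net_gc(s, band)$net,
                              numeric(1))
          floor_val <- stats::qnorm(0.975) * sd(boot_nets)
        }
        pass <- sign(bn$net) != sign(bn_rev$net) &&
          abs(bn$net) > floor_val && abs(bn_rev$net) > floor_val
        tibble(source = c(i, j), target = c(j, i), band = bname,
               gci_fwd = c(bn$gci_fwd, bn$gci_bwd),
               gci_bwd = c(bn$gci_bwd, bn$gci_fwd),
               net = c(bn$net, -bn$net), rgt_pass = pass)
      })
    }, error = function(e) {
      failed[[length(failed) + 1L]] <<- list(pair = c(i, j), message = conditionMessage(e))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  graph <- dplyr::bind_rows(rows)
  if (!is.null(depths) && nrow(graph)) {
    graph <- graph |>
      dplyr::left_join(dplyr::select(depths, channel, source_depth_um = "depth_um"),
                       by = c(source = "channel")) |>
      dplyr::left_join(dplyr::select(depths, channel, target_depth_um = "depth_um"),
                       by = c(target = "channel"))
  }
  attr(graph, "failed_pairs") <- failed
  class(graph) <- c("gc_graph", class(graph))
  graph
}

#' Simulate a stable bivariate VAR process
#'
#' Utility shared by the tests and the synthetic generator's oracles.
#'
#' @param A 2 x 2 x p coefficient array.
#' @param sigma 2 x 2 innovation covariance.
#' @param n_bins samples per trial.
#' @param n_trials number of trials.
#' @param burnin samples discarded at the start of each trial (default 200).
#' @param seed RNG seed.
#' @return list of `x` and `y`, each trials x n_bins.
#' @export
simulate_var <- function(A, sigma, n_bins, n_trials, burnin = 200, seed = 1) {
  p <- dim(A)[3L]
  if (var_spectral_radius(A) >= 1) abort("requested VAR is unstable")
  ch <- chol(sigma)
  with_stream(seed, "simulate-var", {
    x <- matrix(0, n_trials, n_bins)
    y <- matrix(0, n_trials, n_bins)
    ntot <- n_bins + burnin
    for (tr in seq_len(n_trials)) {
      e <- matrix(rnorm(2L * ntot), ntot, 2L) %*% ch
      z <- matrix(0, ntot, 2L)
      for (t in (p + 1L):ntot) {
        acc <- e[t, ]
        for (k in seq_len(p)) acc <- acc + A[, , k] %*% z[t - k, ]
        z[t, ] <- acc
      }
      x[tr, ] <- z[(burnin + 1L):ntot, 1L]
      y[tr, ] <- z[(burnin + 1L):ntot, 2L]
    }
    list(x = x, y = y)
  })
}
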