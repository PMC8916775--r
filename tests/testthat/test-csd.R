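# Inverse CSD, forward model, alignment, depth assignment, QC.

test_that("finite-difference CSD matches the hand-computed value and conventions", {
  # 1 mV bump on the middle of three contacts, 150 um, sigma = 0.3 S/m
  phi <- matrix(c(0, 1000, 0), ncol = 1)
  csd <- compute_icsd(phi)
  expect_equal(csd$values[2, 1], 0.3 * 2e-3 / (150e-6)^2, tolerance = 1e-12)
  expect_gt(csd$values[2, 1], 0)  # sink-positive convention

  # linear-in-depth potential has zero curvature at interior contacts
  lin <- matrix(rep(seq_len(8) * 5, 3), 8, 3)
  expect_lt(max(abs(compute_icsd(lin)$values[2:7, ])), 1e-9)

  # Vaknin endpoint handling keeps all channels
  expect_equal(nrow(compute_icsd(matrix(rnorm(16 * 4), 16))$values), 16)

  # linearity and offset invariance
  a <- matrix(rnorm(10 * 5), 10); b <- matrix(rnorm(10 * 5), 10)
  expect_equal(compute_icsd(2 * a + 3 * b)$values,
               2 * compute_icsd(a)$values + 3 * compute_icsd(b)$values,
               tolerance = 1e-12)
  expect_equal(compute_icsd(a + 17)$values, compute_icsd(a)$values,
               tolerance = 1e-9 * max(abs(compute_icsd(a)$values)))
})

test_that("forward model inverts the CSD operator for charge-balanced maps", {
  # zero in, zero out
  expect_equal(forward_potentials_from_csd(matrix(0, 8, 3)), matrix(0, 8, 3))

  # balanced impulse (sink + flanking return currents) round-trips exactly
  imp <- matrix(0, 16, 1)
  imp[7:9, 1] <- c(-0.5, 1, -0.5) * 2.6e4
  phi <- forward_potentials_from_csd(imp)
  rec <- compute_icsd(phi)$values
  expect_lt(max(abs(rec - imp)) / max(abs(imp)), 1e-9)

  # smooth Gaussian-in-depth sink profile round-trips with correlation 1
  w <- dnorm(1:16, 8, 1.2); w <- w - mean(w)
  csd <- w %o% dnorm(seq(0, 100), 45, 8)
  rec2 <- compute_icsd(forward_potentials_from_csd(csd),
                       time_ms = seq(0, 100))$values
  expect_lt(max(abs(rec2 - csd)) / max(abs(csd)), 1e-9)
  expect_equal(cor(as.vector(rec2), as.vector(csd)), 1, tolerance = 1e-12)

  # unbalanced input is projected onto the conserving subspace, with warning
  expect_warning(out <- forward_potentials_from_csd(matrix(1, 8, 1)),
                 "sum to zero")
  expect_lt(max(abs(compute_icsd(out)$values)), 1e-6)
})

test_that("alignment channel detection finds the early sink and applies the tie rule", {
  w <- dnorm(1:16, 8, 0.8); w <- w - mean(w); w <- w / max(w)
  vals <- w %o% dnorm(seq(0, 100), 45, 6)
  csd <- compute_icsd(forward_potentials_from_csd(vals), time_ms = seq(0, 100))
  al <- find_alignment_channel(csd)
  expect_equal(al$channel, 8)
  expect_equal(al$peak_ms, 45, tolerance = 1)

  # all-negative CSD in the window: explicit failure
  neg <- structure(list(values = matrix(-1, 16, 101), time_ms = seq(0, 100),
                        sigma = 0.3, spacing_um = 150, depth_um = NULL,
                        normalization = "raw"), class = "csd_profile")
  expect_error(find_alignment_channel(neg), "no identifiable sink")

  # tie broken toward the superficial channel with a warning
  tie <- neg
  tie$values[, ] <- 0
  tie$values[7, 46] <- 1; tie$values[9, 46] <- 1
  expect_warning(al2 <- find_alignment_channel(tie), "tied")
  expect_equal(al2$channel, 7)
})

test_that("depth assignment is an affine map with layer 4c at zero", {
  dm <- assign_depths(8, 16, 150)
  expect_equal(dm$depth_um[dm$channel == 5], 450)
  expect_equal(dm$depth_um[dm$channel == 11], -450)
  expect_equal(dm$depth_um[dm$channel == 8], 0)
  expect_equal(dm$compartment[dm$channel == 5], "supragranular")
  expect_true(all(diff(dm$depth_um) == -150))
  expect_true(all(assign_depths(1, 16)$depth_um[-1] < 0))
  expect_error(assign_depths(17, 16), "outside")
})

test_that("session QC applies the early-sink and contact-range criteria", {
  mk_csd <- function(sink_ch, peak_ms) {
    w <- dnorm(1:16, sink_ch, 0.8); w <- w - mean(w)
    vals <- w %o% dnorm(seq(0, 100), peak_ms, 6)
    compute_icsd(forward_potentials_from_csd(vals), time_ms = seq(0, 100))
  }
  good <- qc_session(mk_csd(8, 45))
  expect_true(good$pass)
  expect_equal(good$criteria$status[1:2], c("pass", "pass"))
  expect_equal(good$criteria$status[3], "manual")

  shallow <- qc_session(mk_csd(5, 45))
  expect_false(shallow$pass)
  expect_equal(shallow$criteria$status[2], "fail")

  # sink peaking after the 55 ms search window: criterion 1 fails
  late <- qc_session(mk_csd(8, 80))
  expect_false(late$pass)
  expect_equal(late$criteria$status[1], "fail")

  # manual pattern flag set to fail overrides
  expect_false(qc_session(mk_csd(8, 45), manual_pattern_ok = FALSE)$pass)
})

test_that("sink-peak normalization scales the early sink to one", {
  w <- dnorm(1:16, 8, 0.8); w <- w - mean(w)
  vals <- 3 * (w / max(w)) %o% dnorm(seq(0, 100), 50, 6)
  csd <- compute_icsd(forward_potentials_from_csd(vals), time_ms = seq(0, 100))
  nrm <- normalize_to_sink(csd, 8)
  sel <- nrm$time_ms >= 40 & nrm$time_ms <= 70
  expect_equal(max(nrm$values[8, sel]), 1)
  expect_equal(nrm$normalization, "sink-peak")
})
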