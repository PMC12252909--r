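test_that("driven response normalization and locality of friction cancellation", {
  p <- cochlea_params(N = 600)
  ## passive: normalized peak is exactly 1
  dr0 <- driven_response(p, ker_zero12, 0, 2 * pi * 2000)
  expect_equal(max(dr0$amplitude_norm), 1)
  ## friction canceled only near the 2000 Hz place: that tone is amplified
  ## severalfold, a 300 Hz probe stays essentially passive
  xc <- resonant_position(p, 2 * pi * 2000)
  Cw <- localized_activity(ker_zero12, p, 0.99, center = xc)
  dr2k <- driven_response(p, ker_zero12, Cw, 2 * pi * 2000)
  dr300 <- driven_response(p, ker_zero12, Cw, 2 * pi * 300)
  expect_gt(max(dr2k$amplitude_norm), 3)
  expect_lt(abs(max(dr300$amplitude_norm) - 1), 0.05)
  ## cancellation centred far off the 2000 Hz place: response ~ passive
  Coff <- localized_activity(ker_zero12, p, 0.99, center = 0.9 * p$L)
  dr_off <- driven_response(p, ker_zero12, Coff, 2 * pi * 2000)
  expect_lt(abs(max(dr_off$amplitude_norm) - 1), 0.1)
})

test_that("stationary rms solves the Lyapunov equation and scales with noise", {
  p <- cochlea_params(N = 40)
  ss <- build_jacobian(p, ker_zero12, 0)
  eig <- eigen(ss$J)
  ## full-covariance residual check of the diagonalization route
  lam <- eig$values
  V <- eig$vectors
  w <- solve(V, ss$B)
  S <- -outer(w, w) / outer(lam, lam, "+")
  Sig <- Re(V %*% S %*% t(V))
  resid <- ss$J %*% Sig + Sig %*% t(ss$J) + ss$B %*% t(ss$B)
  expect_lt(max(abs(resid)) / max(abs(ss$B %*% t(ss$B))), 1e-8)
  ## the exported rms equals the height diagonal of that covariance
  rms <- stationary_rms(ss, 1, eig = eig)
  expect_equal(rms, sqrt(pmax(diag(Sig)[ss$index_map$h], 0)), tolerance = 1e-9)
  ## linear scale-out in the noise intensity
  expect_equal(stationary_rms(ss, 3, eig = eig), 3 * rms, tolerance = 1e-12)
  ## unstable systems have no stationary state
  Cover <- activity_for_fraction(ker_exp2, p, 1.02)
  ss_bad <- build_jacobian(p, ker_exp2, Cover)
  expect_error(stationary_rms(ss_bad, 1), class = "activecochlea_unstable")
})

test_that("stationary rms agrees with an Euler-Maruyama oracle", {
  ## scaled-down cochlea so the explicit scheme is stable with a modest dt
  p <- slow_params(N = 6)
  ss <- build_jacobian(p, ker_inst, 0.5)
  rms_lyap <- stationary_rms(ss, noise_sd = 1)
  hsq <- em_height_sq(ss, noise_sd = 1, dt = 1e-5, t_burn = 1.5,
                      t_keep = 1.5, n_rep = 128L, seed = 42L)
  m <- rowMeans(hsq)
  se <- apply(hsq, 1, stats::sd) / sqrt(ncol(hsq))
  ## the explicit scheme carries a small positive O(dt) variance bias
  ## (~ |lambda|^2 dt / 2|Re lambda|, ~5% here), within the Monte-Carlo band
  expect_true(all(abs(m - rms_lyap^2) <= 3 * se + 0.06 * rms_lyap^2))
  ## and the oracle is informative: tight relative agreement
  expect_lt(max(abs(m - rms_lyap^2) / rms_lyap^2), 0.15)
})

test_that("rms height is hypersensitive to activity strength near full cancellation", {
  ## instantaneous-derivative kernel: C = 1 cancels friction exactly, so
  ## the rms at a fixed place diverges as C -> 1; the logarithmic
  ## susceptibility d log(rms) / d log(C) is >> 1 near the bifurcation,
  ## and sharpens with grid refinement as the residual discretization
  ## damping (~ 1/N) shrinks
  slope_at <- function(N) {
    p <- cochlea_params(N = N)
    rms_at <- function(C)
      stationary_rms(build_jacobian(p, ker_inst, C), 1)[N %/% 2]
    (log(rms_at(0.995)) - log(rms_at(0.965))) / (log(0.995) - log(0.965))
  }
  s300 <- slope_at(300)
  s600 <- slope_at(600)
  expect_gt(s600, 5)
  expect_gt(s600, s300)
})

## Self-tuning runs shared across the remaining blocks: zero-derivative
## kernel (stable extended modes), modest grid.
p_st <- cochlea_params(N = 64)
ts10 <- self_tune(p_st, ker_zero12, h0_multiple = 10, n_steps = 400)

test_that("slow feedback parks every segment at its amplification target", {
  expect_true(ts10$converged)
  x <- cochlea_grid(p_st)$x
  interior <- x <= 0.9 * p_st$L
  expect_lt(max(abs(1 - ts10$rms[interior] / ts10$h0[interior])), 0.02)
  ## stays on the stable side of the edge of instability throughout
  eps <- 1e-6 * p_st$xi
  expect_true(all(ts10$trajectory$max_re_lambda < eps))
  expect_lte(max(ts10$modes$table$re), eps)
  ## activity magnitude is nonnegative along the amplifying orientation
  expect_true(all(ts10$orientation * as.numeric(ts10$C) >= 0))
})

test_that("self-tuning drives localized decay rates towards the edge of instability", {
  md0 <- eigenmodes(build_jacobian(p_st, ker_zero12, 0), values_only = TRUE)
  re0 <- stats::median(abs(md0$table$re[md0$table$class == "localized"]))
  reT <- stats::median(abs(ts10$modes$table$re[
    ts10$modes$table$class == "localized"]))
  expect_lt(reT, 0.05 * re0)
  ## tuned state shows slightly negative net friction above resonance
  x <- cochlea_grid(p_st)$x
  i <- 32
  wres <- resonant_frequency_active(ker_zero12, as.numeric(ts10$C)[i], p_st, x[i])
  w_above <- seq(1.05 * wres, 1.8 * wres, length.out = 100)
  expect_lt(min(net_friction(ker_zero12, as.numeric(ts10$C)[i], p_st,
                             x[i], w_above)), 0)
})

test_that("the tuned activity depends only weakly on the target height", {
  ts5 <- self_tune(p_st, ker_zero12, h0_multiple = 5, n_steps = 400)
  expect_true(ts5$converged)
  interior <- seq_len(floor(0.9 * p_st$N))
  rel <- abs(as.numeric(ts5$C)[interior] - as.numeric(ts10$C)[interior]) /
    abs(as.numeric(ts10$C)[interior])
  ## doubling h0 moves C by a few percent only
  expect_lt(stats::median(rel), 0.10)
})

test_that("a dead region leaves distant segments' amplification intact", {
  ts <- experiment_dead_zone(p_st, ker_zero12, h0_multiple = 5, n_steps = 400)
  x <- cochlea_grid(p_st)$x
  in_zone <- x > ts$zone[1] & x < ts$zone[2]
  expect_true(all(as.numeric(ts$C)[in_zone] == 0))
  ## distant active segments still reach the target
  far <- !in_zone & (x < ts$zone[1] - 0.1 * p_st$L) & x > 0.1 * p_st$L
  expect_lt(max(abs(1 - ts$rms[far] / ts$h0[far])), 0.05)
  ## dead segments near the zone edge are partially amplified by neighbours
  edge <- which(in_zone)[1]
  expect_gt(ts$rms[edge] / ts$rms_passive[edge], 1.5)
  expect_lt(ts$rms[edge] / ts$h0[edge], 1)
  ## an empty zone reduces to plain self-tuning
  ts_null <- experiment_dead_zone(p_st, ker_zero12, h0_multiple = 5,
                                  zone = NULL, n_steps = 400)
  ts_plain <- self_tune(p_st, ker_zero12, h0_multiple = 5, n_steps = 400)
  expect_equal(as.numeric(ts_null$C), as.numeric(ts_plain$C))
})

test_that("self-tuning tolerates a noisy stiffness profile", {
  ts <- experiment_stiffness_noise(p_st, ker_zero12, h0_multiple = 5,
                                   noise_sd = 0.01, seed = 7L, n_steps = 400)
  ## similar average enhancement as the clean profile
  enh <- mean(ts$rms / ts$rms_passive)
  expect_gt(enh, 3)
  expect_true(all(ts$orientation * as.numeric(ts$C) >= 0))
  ## zero noise reproduces the clean run exactly
  ts0 <- experiment_stiffness_noise(p_st, ker_zero12, h0_multiple = 5,
                                    noise_sd = 0, seed = 7L, n_steps = 400)
  ts_plain <- self_tune(p_st, ker_zero12, h0_multiple = 5, n_steps = 400)
  expect_equal(as.numeric(ts0$C), as.numeric(ts_plain$C))
  ## an extreme draw that kills the stiffness is rejected
  expect_error(experiment_stiffness_noise(p_st, ker_zero12, h0_multiple = 5,
                                          noise_sd = 5, seed = 1L),
               "positive")
})
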