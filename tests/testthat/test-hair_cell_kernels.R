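p40 <- cochlea_params(N = 40)

test_that("closed-form transfer matches Fourier quadrature of the time-domain kernel", {
  x <- 0.018
  omegas <- 2 * pi * c(30, 300, 1200)
  for (nm in names(all_regular_kernels)) {
    ker <- all_regular_kernels[[nm]]
    sc <- transfer_scale(ker, p40, x)
    for (w in omegas) {
      expect_lt(Mod(kernel_transfer(ker, p40, x, w) -
                    transfer_by_quadrature(ker, p40, x, w)) / sc,
                1e-6, label = paste(nm, "at", round(w)))
    }
  }
})

test_that("kernels are causal and conjugate-symmetric", {
  x <- 0.01
  for (nm in names(all_regular_kernels)) {
    ker <- all_regular_kernels[[nm]]
    expect_identical(kernel_time(ker, p40, x, c(-1e-3, -1e-7)), c(0, 0),
                     label = nm)
    w <- 2 * pi * c(50, 700, 5000)
    expect_equal(kernel_transfer(ker, p40, x, -w),
                 Conj(kernel_transfer(ker, p40, x, w)), label = nm)
  }
  expect_equal(kernel_transfer(ker_inst, p40, 0.01, -300),
               Conj(kernel_transfer(ker_inst, p40, 0.01, 300)))
})

test_that("family-defining moment conditions hold analytically and by quadrature", {
  x <- 0.02
  wres <- resonant_frequency_passive(p40, x)
  ## single_exp at omega = 0: xi omega0^2 / r, real and positive
  expect_equal(kernel_transfer(ker_exp2, p40, x, 0),
               complex(real = p40$xi * p40$omega0^2 / (2 * wres)))
  ## approx_derivative: zero mean (static shift has no effect)
  expect_equal(abs(kernel_transfer(ker_apx, p40, x, 0)), 0, tolerance = 1e-20)
  tmax <- 80 / (0.5 * wres)
  m0_scale <- stats::integrate(function(t) abs(kernel_time(ker_apx, p40, x, t)),
                               0, tmax, subdivisions = 4000L,
                               rel.tol = 1e-10)$value
  m0 <- stats::integrate(function(t) kernel_time(ker_apx, p40, x, t),
                         0, tmax, subdivisions = 4000L, rel.tol = 1e-8,
                         abs.tol = 1e-8 * m0_scale)$value
  expect_lt(abs(m0) / m0_scale, 1e-7)
  ## zero_derivative: vanishing transfer slope at omega = 0 ...
  dw <- 1e-3
  slope <- (kernel_transfer(ker_zero12, p40, x, dw) -
            kernel_transfer(ker_zero12, p40, x, -dw)) / (2 * dw)
  scale <- abs(kernel_transfer(ker_zero12, p40, x, wres)) / wres
  expect_lt(abs(slope) / scale, 1e-8)
  ## ... equivalently a vanishing first moment of g, by quadrature
  m1_scale <- stats::integrate(function(t)
    abs(kernel_time(ker_zero12, p40, x, t)) * t, 0, tmax,
    subdivisions = 4000L, rel.tol = 1e-10)$value
  m1 <- stats::integrate(function(t) kernel_time(ker_zero12, p40, x, t) * t,
                         0, tmax, subdivisions = 4000L, rel.tol = 1e-8,
                         abs.tol = 1e-8 * m1_scale)$value
  expect_lt(abs(m1) / m1_scale, 1e-7)
})

test_that("confluent (equal-rate) kernels are the analytic limit of nearby rates", {
  x <- 0.015
  w <- 2 * pi * 400
  for (fam in c("approx_derivative", "zero_derivative")) {
    kc <- hair_cell_kernel(fam, alpha1 = 1.5, alpha2 = 1.5)
    gc <- kernel_transfer(kc, p40, x, w)
    ## limit of the split-rate family, rescaled by the removable factor
    eps <- 1e-6
    ks <- hair_cell_kernel(fam, alpha1 = 1.5, alpha2 = 1.5 + eps)
    r1 <- 1.5 * resonant_frequency_passive(p40, x)
    r2 <- (1.5 + eps) * resonant_frequency_passive(p40, x)
    gs <- kernel_transfer(ks, p40, x, w) * r1 / (r2 - r1)
    expect_equal(gc, gs, tolerance = 1e-4, label = fam)
  }
})

test_that("unknown kernel families and bad rates are rejected", {
  expect_error(hair_cell_kernel("boxcar"), "arg")
  expect_error(hair_cell_kernel("single_exp"), "alpha")
  expect_error(hair_cell_kernel("zero_derivative", alpha1 = 1, alpha2 = -2),
               "positive")
  expect_error(kernel_time(ker_inst, p40, 0.01, 0.1), "instant")
})

test_that("fraction-f activity pins net friction to 1 - f on the resonance line", {
  p <- cochlea_params(N = 30)
  x <- cochlea_grid(p)$x
  for (nm in c("single_exp", "approx_derivative", "zero_derivative")) {
    ker <- all_regular_kernels[[nm]]
    for (f in c(0.90, 0.99)) {
      Cf <- activity_for_fraction(ker, p, f)
      Xi <- net_friction(ker, Cf, p, x, attr(Cf, "omega_res"))
      expect_equal(Xi, rep(1 - f, p$N), tolerance = 1e-10,
                   label = paste(nm, f))
      ## fixed point: recomputing the resonance from the returned C
      ## reproduces the stored resonance
      w2 <- resonant_frequency_active(ker, Cf, p, x)
      expect_equal(w2, attr(Cf, "omega_res"), tolerance = 1e-8)
    }
  }
  ## f = 0: passive
  C0 <- activity_for_fraction(ker_exp2, p, 0)
  expect_identical(as.numeric(C0), rep(0, p$N))
})

test_that("activity sign follows the kernel orientation (two-exponential swap identity)", {
  p <- cochlea_params(N = 12)
  x <- cochlea_grid(p)$x
  C12 <- activity_for_fraction(ker_zero12, p, 0.99)
  ker_sw <- hair_cell_kernel("zero_derivative", alpha1 = 2, alpha2 = 1)
  C21 <- activity_for_fraction(ker_sw, p, 0.99)
  expect_true(all(as.numeric(C12) < 0)) # alpha1 < alpha2: Im g~ > 0 at resonance
  expect_true(all(as.numeric(C21) > 0))
  ## the physical active impedance C * g~ is identical for both orderings
  w <- 2 * pi * 500
  expect_equal(as.numeric(C12) * kernel_transfer(ker_zero12, p, x, w),
               as.numeric(C21) * kernel_transfer(ker_sw, p, x, w),
               tolerance = 1e-9)
})

test_that("total impedance and net friction reduce correctly in limiting cases", {
  p <- cochlea_params(N = 25)
  x <- cochlea_grid(p)$x
  w <- 2 * pi * 800
  expect_equal(total_impedance(ker_exp2, 0, p, x, w),
               passive_impedance(p, x, w))
  expect_equal(net_friction(ker_exp2, 0, p, x, w), rep(1, p$N))
  expect_error(net_friction(ker_exp2, 0, p, x, 0), "omega = 0")
  ## single_exp net friction increases monotonically in frequency at fixed x
  Cf <- activity_for_fraction(ker_exp2, p, 0.99)
  x0 <- x[12]
  wgrid <- seq(5, 1.5 * resonant_frequency_passive(p, x0), length.out = 300)
  Xi <- net_friction(ker_exp2, as.numeric(Cf)[12], p, x0, wgrid)
  expect_true(all(diff(Xi) > 0))
  ## conjugate symmetry of the total impedance
  expect_equal(total_impedance(ker_exp2, Cf, p, x, -w),
               Conj(total_impedance(ker_exp2, Cf, p, x, w)))
})

test_that("active resonance matches passive for C = 0 and purely imaginary kernels", {
  p <- cochlea_params(N = 20)
  x <- cochlea_grid(p)$x
  expect_equal(resonant_frequency_active(ker_exp2, 0, p, x),
               resonant_frequency_passive(p, x))
  expect_equal(resonant_frequency_active(ker_inst, 0.8, p, x),
               resonant_frequency_passive(p, x))
  ## small activity increments shift the resonance proportionally to Re g~
  x0 <- 0.02
  w0 <- resonant_frequency_passive(p, x0)
  dC <- 1e-4
  shift <- resonant_frequency_active(ker_exp2, dC, p, x0) - w0
  predicted <- dC * Re(kernel_transfer(ker_exp2, p, x0, w0)) / (2 * w0)
  expect_equal(shift, predicted, tolerance = 1e-3)
})
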