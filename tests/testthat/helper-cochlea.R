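## Shared fixtures and oracles, all built in code.

## Standard kernels used across tests
ker_exp2 <- hair_cell_kernel("single_exp", alpha = 2)
ker_zero12 <- hair_cell_kernel("zero_derivative", alpha1 = 1, alpha2 = 2)
ker_apx <- hair_cell_kernel("approx_derivative", alpha1 = 0.5, alpha2 = 1.5)
ker_inst <- hair_cell_kernel("instant_derivative")

all_regular_kernels <- list(
  single_exp = ker_exp2,
  approx_derivative = ker_apx,
  approx_confluent = hair_cell_kernel("approx_derivative", alpha1 = 1.5, alpha2 = 1.5),
  zero_derivative = ker_zero12,
  zero_confluent = hair_cell_kernel("zero_derivative", alpha1 = 2, alpha2 = 2)
)

## A slow, mild-stiffness parameter set for time-integration oracles:
## same model structure, rates scaled down so explicit schemes are
## stable. The light fluid (small rho) puts the coarse grid in the
## strong-coupling regime where every mode decays at an O(xi) rate, so
## stationarity is reached within a short simulated window.
slow_params <- function(N = 6L) {
  cochlea_params(N = N, rho = 0.5, omega0 = 2 * pi * 40,
                 omega_ow = 2 * pi * 25, k = 40, xi = 20, xi_ow = 30)
}

## Independent quadrature oracle for the kernel transfer: numerically
## Fourier-transform the stated time-domain kernel with adaptive
## quadrature (real and imaginary parts separately).
transfer_by_quadrature <- function(kernel, params, x, omega) {
  tmax <- 80 / min(kernel_rates_for_test(kernel, params, x))
  re <- stats::integrate(function(t) kernel_time(kernel, params, x, t) *
                           cos(omega * t), 0, tmax,
                         subdivisions = 4000L, rel.tol = 1e-10,
                         abs.tol = 1e-12)$value
  im <- stats::integrate(function(t) -kernel_time(kernel, params, x, t) *
                           sin(omega * t), 0, tmax,
                         subdivisions = 4000L, rel.tol = 1e-10,
                         abs.tol = 1e-12)$value
  complex(real = re, imaginary = im)
}

## typical magnitude of g~ for scale-relative comparisons
transfer_scale <- function(kernel, params, x) {
  params$xi * params$omega0^2 / mean(kernel_rates_for_test(kernel, params, x))
}

kernel_rates_for_test <- function(kernel, params, x) {
  w <- resonant_frequency_passive(params, x)
  if (kernel$family == "single_exp") kernel$alpha * w
  else c(kernel$alpha1, kernel$alpha2) * w
}

## Euler-Maruyama oracle for the stationary rms under white-noise drive:
## an ensemble of replicas stepped with the explicit scheme
##   X <- X + dt J X + sqrt(dt) B sd eta.
## Returns the per-replica mean of h^2 (rows: height entries, cols:
## replicas averaged over the retained samples), from which a Monte-Carlo
## standard error across independent replicas can be formed.
em_height_sq <- function(ss, noise_sd, dt, t_burn, t_keep, n_rep, seed,
                         thin = 25L) {
  set.seed(seed)
  D <- nrow(ss$J)
  ih <- ss$index_map$h
  X <- matrix(0, D, n_rep)
  Jdt <- ss$J * dt
  Bs <- ss$B * noise_sd * sqrt(dt)
  n_burn <- ceiling(t_burn / dt)
  n_keep <- ceiling(t_keep / dt)
  for (i in seq_len(n_burn))
    X <- X + Jdt %*% X + Bs %o% stats::rnorm(n_rep)
  acc <- matrix(0, length(ih), n_rep)
  n_acc <- 0L
  for (i in seq_len(n_keep)) {
    X <- X + Jdt %*% X + Bs %o% stats::rnorm(n_rep)
    if (i %% thin == 0L) {
      acc <- acc + X[ih, , drop = FALSE]^2
      n_acc <- n_acc + 1L
    }
  }
  acc / n_acc
}
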