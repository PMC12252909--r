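#' Analytic net-friction instability criterion
#'
#' The extended modes live below the local resonance, so a kernel
#' destabilizes them when the net friction dips negative at any frequency
#' below resonance. Fixing a position `x0`, the criterion scans
#' `Xi_net(x0, omega)` on a dense logarithmic grid over
#' `(0, omega_res(x0))` and declares instability if the minimum is
#' negative. This needs no eigenvectors and no oval-window coupling, yet
#' predicts the eigenvalue verdict well; disagreements (attributable to
#' oval-window dissipation) are expected to be rare but real.
#'
#' @inheritParams total_impedance
#' @param x0 probe position (m); the net friction is scanned there.
#' @param C activity strength *at* `x0` (scalar).
#' @param n_omega number of log-spaced frequencies in the scan.
#' @param omega_min_frac lower end of the scan as a fraction of the
#'   resonance frequency.
#' @return list with `stable` (logical: no sub-resonant negative
#'   friction), `min_Xi`, `omega_min` (minimizing frequency, rad/s),
#'   `omega_res` (active resonance at `x0`).
#' @export
friction_criterion <- function(kernel, C, params, x0 = 0.025,
                               n_omega = 400L, omega_min_frac = 1e-3) {
  C <- as.numeric(C)[1L]
  wres <- resonant_frequency_active(kernel, C, params, x0)
  wgrid <- exp(seq(log(omega_min_frac * wres), log(wres),
                   length.out = n_omega))
  ## exclude the resonance endpoint itself (Xi = 1 - f >= 0 by construction)
  wgrid <- wgrid[-n_omega]
  Xi <- net_friction(kernel, C, params, x0, wgrid)
  i <- which.min(Xi)
  list(stable = Xi[i] >= 0, min_Xi = Xi[i], omega_min = wgrid[i],
       omega_res = wres)
}

#' Kernel-parameter stability phase diagram
#'
#' For each kernel parameter point and each friction-cancellation fraction
#' `f`, records two independent stability verdicts: the analytic
#' sub-resonant net-friction criterion evaluated at a representative
#' position `x0`, and the full eigenvalue verdict
#' (`max Re lambda <= eps`) from building and diagonalizing the Jacobian
#' with the fraction-`f` activity profile. Disagreements are preserved,
#' never reconciled.
#'
#' @param family kernel family name (see [hair_cell_kernel()]).
#' @param alpha_grid for `single_exp`: numeric vector of `alpha`; for the
#'   two-exponential families: a data.frame/list with components `alpha1`
#'   and `alpha2` (e.g. from [expand.grid()]).
#' @param f_list fractions of friction canceled to test.
#' @param params a [cochlea_params()]; its `N` sets the eigenvalue-check
#'   grid (moderate `N` suffices because the extended-mode structure
#'   plateaus at small `N`).
#' @param x0 probe position for the analytic criterion (m).
#' @param eps_stability instability tolerance on `Re lambda` (1/s);
#'   default `1e-6 * xi`, relative to the damping scale, because full
#'   cancellation parks eigenvalues numerically on the axis.
#' @return data.frame with columns `alpha1`, `alpha2` (equal to `alpha`
#'   for `single_exp`), `f`, `criterion_stable`, `eigen_stable`,
#'   `max_re_lambda`, `min_Xi`. Kernel build failures yield `NA` verdicts.
#' @export
phase_diagram <- function(family, alpha_grid, f_list = c(0.90, 0.99, 1.00),
                          params = cochlea_params(N = 300L), x0 = 0.025,
                          eps_stability = 1e-6 * params$xi) {
  pts <- if (family == "single_exp") {
    data.frame(alpha1 = as.numeric(alpha_grid),
               alpha2 = as.numeric(alpha_grid))
  } else {
    data.frame(alpha1 = alpha_grid$alpha1, alpha2 = alpha_grid$alpha2)
  }
  out <- vector("list", nrow(pts) * length(f_list))
  kk <- 0L
  for (i in seq_len(nrow(pts))) {
    ker <- if (family == "single_exp")
      hair_cell_kernel("single_exp", alpha = pts$alpha1[i])
    else
      hair_cell_kernel(family, alpha1 = pts$alpha1[i], alpha2 = pts$alpha2[i])
    for (f in f_list) {
      kk <- kk + 1L
      row <- data.frame(alpha1 = pts$alpha1[i], alpha2 = pts$alpha2[i],
                        f = f, criterion_stable = NA, eigen_stable = NA,
                        max_re_lambda = NA_real_, min_Xi = NA_real_)
      res <- try({
        C0 <- as.numeric(activity_for_fraction(ker, params, f, x = x0))
        fc <- friction_criterion(ker, C0, params, x0 = x0)
        Cf <- activity_for_fraction(ker, params, f)
        ss <- build_jacobian(params, ker, Cf)
        mre <- max(Re(eigen(ss$J, only.values = TRUE)$values))
        row$criterion_stable <- fc$stable
        row$min_Xi <- fc$min_Xi
        row$eigen_stable <- mre <= eps_stability
        row$max_re_lambda <- mre
      }, silent = TRUE)
      if (inherits(res, "try-error"))
        attr(row, "error") <- as.character(res)
      out[[kk]] <- row
    }
  }
  do.call(rbind, out)
}
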