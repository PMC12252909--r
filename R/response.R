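#' Pure-tone driven response
#'
#' Solves the frequency-domain operator at the drive frequency and reports
#' the height amplitude profile, normalized to the peak response of the
#' *passive* cochlea at the same frequency and amplitude (so a passive run
#' peaks at exactly 1 and active amplification reads off directly).
#'
#' @inheritParams frequency_operator
#' @param amplitude real ear-canal pressure amplitude (Pa).
#' @return object of class `"driven_response"`: list with `x`, `h`
#'   (complex), `amplitude_norm` (`|h|` over the passive peak),
#'   `passive_peak`, `omega`, `amplitude`.
#' @examples
#' p <- cochlea_params(N = 200)
#' ker <- hair_cell_kernel("single_exp", alpha = 2)
#' dr <- driven_response(p, ker, 0, omega = 2 * pi * 2000)
#' max(dr$amplitude_norm)  # 1: passive by construction
#' @export
driven_response <- function(params, kernel, C, omega, amplitude = 1) {
  sol <- frequency_operator(params, kernel, C, omega, P_ec = amplitude)
  ref <- frequency_operator(params, kernel, 0, omega, P_ec = amplitude)
  pk <- max(abs(ref$h))
  structure(list(x = sol$x, h = sol$h, amplitude_norm = abs(sol$h) / pk,
                 passive_peak = pk, omega = omega, amplitude = amplitude),
            class = "driven_response")
}

#' @export
print.driven_response <- function(x, ...) {
  cat("<driven_response> ", x$omega / (2 * pi), " Hz, peak ",
      sprintf("%0.3g", max(x$amplitude_norm)), "x the passive peak at x = ",
      sprintf("%0.4g", x$x[which.max(x$amplitude_norm)]), " m\n", sep = "")
  invisible(x)
}

#' Spatially windowed friction cancellation
#'
#' An activity profile that cancels a fraction `f` of friction only inside
#' a Gaussian window centred on `center`: `C(x) = C_f(x) exp(-(x -
#' center)^2 / (2 width^2))`. Used to demonstrate that cancellation acts
#' locally: only tones resonant near `center` are amplified.
#'
#' @inheritParams activity_for_fraction
#' @param center window centre (m), e.g. `resonant_position(params, omega)`.
#' @param width Gaussian standard deviation (m); the default, 2% of the
#'   membrane length, covers the sharp peak of one localized mode.
#' @return an [activity_profile()] on the grid.
#' @export
localized_activity <- function(kernel, params, f, center,
                               width = 0.02 * params$L) {
  Cf <- activity_for_fraction(kernel, params, f)
  x <- attr(Cf, "x")
  w <- exp(-(x - center)^2 / (2 * width^2))
  activity_profile(as.numeric(Cf) * w, x,
                   provenance = sprintf("fraction f = %g windowed at %g m", f, center))
}

## Stationary covariance of dX = J X dt + B sigma dW via diagonalization:
## with J = V Lam V^{-1} and w = V^{-1} B, the transformed covariance is
## S_ij = -sigma^2 w_i w_j / (lam_i + lam_j) and Sigma = V S V^T (plain
## transpose: the Lyapunov equation J Sigma + Sigma J^T + sigma^2 B B^T = 0
## is over reals). Returns the diagonal of Sigma on `rows`.
lyapunov_diag <- function(eig, B, sigma, rows) {
  lam <- eig$values
  V <- eig$vectors
  w <- solve(V, B)
  S <- -(sigma^2) * outer(w, w) / outer(lam, lam, "+")
  Vh <- V[rows, , drop = FALSE]
  Re(rowSums((Vh %*% S) * Vh))
}

#' Stationary rms height under white-noise ear-canal drive
#'
#' Models incoming sound as uncorrelated Gaussian pressure noise
#' `P_ec(t) = eta(t)` with intensity `noise_sd` (units Pa sqrt(s)) and
#' solves the stationary covariance (continuous Lyapunov) equation
#' `J Sigma + Sigma J^T + noise_sd^2 B B^T = 0` through the
#' eigendecomposition of `J`. The rms height per segment is the square
#' root of the height-block diagonal of `Sigma`; it scales linearly in
#' `noise_sd`.
#'
#' @param ss a [build_jacobian()] state space; must be strictly stable.
#' @param noise_sd noise intensity of the ear-canal pressure.
#' @param eig optional precomputed `eigen(ss$J)`.
#' @return numeric vector of rms heights (m) per segment.
#' @export
stationary_rms <- function(ss, noise_sd = 1, eig = NULL) {
  stopifnot(inherits(ss, "cochlea_state_space"))
  if (is.null(eig)) eig <- eigen(ss$J)
  if (max(Re(eig$values)) >= 0)
    stop(structure(class = c("activecochlea_unstable", "error", "condition"),
                   list(message = paste0(
                     "system is not strictly stable (max Re lambda = ",
                     format(max(Re(eig$values))),
                     "); no stationary state exists"),
                     call = sys.call())))
  d <- lyapunov_diag(eig, ss$B, noise_sd, ss$index_map$h)
  sqrt(pmax(d, 0))
}

#' Self-tuning of hair-cell activity by order-parameter feedback
#'
#' Evolves the activity strength of every segment by slow feedback from
#' the local rms height: `tau_a dC(x)/dt = 1 - <h(x,t)^2> / h0(x)^2`,
#' where the target `h0(x)` is a multiple of the passive rms profile and
#' the noise average is taken quasi-statically — the stationary rms under
#' white-noise drive is recomputed after every explicit slow Euler step
#' (timescale separation: the feedback is far slower than any mechanical
#' timescale, so the fast dynamics equilibrate between steps and `tau_a`
#' itself drops out of the fixed point).
#'
#' The amplifying orientation of `C` is determined once from the sign of
#' `Im g~` at resonance (positive `C` amplifies for kernels with
#' `Im g~ < 0` there; the mirrored orientation of the two-exponential
#' families is handled transparently), and the activity magnitude is
#' clipped at zero from below. Whenever a step leaves the system without a
#' stationary state (some `Re lambda >= 0`), the rms ratio term is
#' replaced by a large constant so that feedback drives activity back
#' down, mimicking the physical divergence of oscillation amplitude. The
#' per-segment step is scaled by the local full-cancellation strength
#' `|C_100(x)|`, which spans orders of magnitude along the membrane, so
#' that every segment approaches its own critical point at a comparable
#' relative rate.
#'
#' @param params a [cochlea_params()].
#' @param kernel a [hair_cell_kernel()] whose extended modes are stable at
#'   the working `f` (e.g. `zero_derivative` with `alpha1 * alpha2 > 1`).
#' @param h0_multiple target rms as a multiple of the passive rms.
#' @param tau_a feedback timescale (s); only sets the time axis of the
#'   reported trajectory, not the fixed point.
#' @param noise_sd ear-canal noise intensity (linear scale-out: the
#'   converged activity is independent of it).
#' @param init_C initial activity magnitudes (length `N` or scalar).
#' @param n_steps maximum number of slow Euler steps.
#' @param dt_frac slow step as a fraction of `tau_a`.
#' @param tol convergence tolerance on `|1 - rms/h0|`. Convergence is
#'   judged on active segments with `x <= 0.9 L`: the apex-most segments
#'   equilibrate below target, limited by the stability of the collective
#'   extended modes (pushing harder would destabilize them), and that
#'   shortfall is a feature of the steady state, not a failure to
#'   converge. The full error field is still reported.
#' @param pinned_zero optional logical mask (length `N`): segments whose
#'   activity is pinned to zero (dead regions).
#' @param record_every record the trajectory every this many steps.
#' @return object of class `"tuning_state"`: list with `C` (final signed
#'   [activity_profile()]), `rms`, `h0`, `rms_passive`, `converged`,
#'   `steps`, `trajectory` (data.frame: `step`, `time`, `max_re_lambda`,
#'   `max_ratio_err`, `mean_C`), `C_trace` (matrix of recorded activity
#'   magnitudes), `modes` (final [eigenmodes()], eigenvalues only),
#'   `orientation`, `params`, `kernel`.
#' @export
self_tune <- function(params, kernel, h0_multiple = 10, tau_a = 1,
                      noise_sd = 1, init_C = 0, n_steps = 600L,
                      dt_frac = 1 / 50, tol = 0.02, pinned_zero = NULL,
                      record_every = 10L) {
  N <- params$N
  x <- cochlea_grid(params)$x
  if (is.null(pinned_zero)) pinned_zero <- rep(FALSE, N)
  stopifnot(length(pinned_zero) == N)

  ## passive reference and target
  ss0 <- build_jacobian(params, kernel, 0)
  eig0 <- eigen(ss0$J)
  rms_passive <- stationary_rms(ss0, noise_sd, eig = eig0)
  h0 <- h0_multiple * rms_passive

  ## amplifying orientation and local strength scale from full cancellation
  C100 <- activity_for_fraction(kernel, params, 1)
  orientation <- sign(as.numeric(C100)[ceiling(N / 2)])
  scale100 <- abs(as.numeric(C100))

  a <- pmax(rep_len(abs(as.numeric(init_C)), N), 0)
  a[pinned_zero] <- 0
  eps_stab <- 1e-6 * params$xi
  interior <- !pinned_zero & x <= 0.9 * params$L
  if (!any(interior)) interior <- !pinned_zero

  n_rec <- 0L
  traj <- vector("list", n_steps %/% record_every + 2L)
  C_trace <- list()
  converged <- FALSE
  step <- 0L
  rms <- rms_passive
  repeat {
    step <- step + 1L
    ss <- build_jacobian(params, kernel, orientation * a)
    eig <- eigen(ss$J)
    mre <- max(Re(eig$values))
    if (mre >= 0) {
      ratio <- rep(10, N) # no stationary state: drive activity down
    } else {
      rms <- sqrt(pmax(lyapunov_diag(eig, ss$B, noise_sd, ss$index_map$h), 0))
      ratio <- (rms / h0)^2
    }
    err <- abs(1 - sqrt(ratio))
    if (step %% record_every == 1L || step == n_steps) {
      n_rec <- n_rec + 1L
      traj[[n_rec]] <- data.frame(step = step, time = step * dt_frac * tau_a,
                                  max_re_lambda = mre,
                                  max_ratio_err = max(err[!pinned_zero]),
                                  mean_C = mean(a))
      C_trace[[n_rec]] <- a
    }
    if (mre < eps_stab && max(err[interior]) < tol) {
      converged <- TRUE
      break
    }
    if (step >= n_steps) break
    a <- pmax(a + dt_frac * scale100 * (1 - ratio), 0)
    a[pinned_zero] <- 0
  }
  if (!converged)
    warning("self-tuning did not reach tolerance ", tol, " within ",
            n_steps, " steps (max |1 - rms/h0| = ",
            format(max(err[interior])), " away from the apex); ",
            "returning partial result")

  Cfinal <- activity_profile(orientation * a, x, provenance = "self-tuned")
  ssf <- build_jacobian(params, kernel, Cfinal)
  structure(list(C = Cfinal, rms = rms, h0 = h0, rms_passive = rms_passive,
                 converged = converged, steps = step,
                 trajectory = do.call(rbind, traj[seq_len(n_rec)]),
                 C_trace = do.call(rbind, C_trace),
                 modes = eigenmodes(ssf, values_only = TRUE),
                 orientation = orientation, params = params, kernel = kernel),
            class = "tuning_state")
}

#' @export
print.tuning_state <- function(x, ...) {
  cat("<tuning_state> ", if (x$converged) "converged" else "NOT converged",
      " after ", x$steps, " slow steps\n", sep = "")
  cat(sprintf("  max Re lambda = %0.4g 1/s, median rms/h0 = %0.3f\n",
              max(x$modes$table$re), stats::median(x$rms / x$h0)))
  invisible(x)
}

#' Self-tuning with a dead (inactive) region
#'
#' Runs [self_tune()] with activity pinned to zero inside `zone` (default:
#' the middle 10% of the membrane). Segments away from the dead region
#' still reach their amplification target; inactive segments near the zone
#' edges are partially amplified by their active neighbours.
#'
#' @inheritParams self_tune
#' @param zone numeric length-2 interval (m) within `[0, L]`; `NULL` for
#'   no dead region (identical to plain [self_tune()]).
#' @return a `"tuning_state"` (see [self_tune()]) with an extra `zone`
#'   element.
#' @export
experiment_dead_zone <- function(params, kernel, h0_multiple = 5,
                                 zone = c(0.45, 0.55) * params$L, ...) {
  x <- cochlea_grid(params)$x
  pinned <- if (is.null(zone)) NULL else (x > zone[1] & x < zone[2])
  ts <- self_tune(params, kernel, h0_multiple = h0_multiple,
                  pinned_zero = pinned, ...)
  ts$zone <- zone
  ts
}

#' Self-tuning on a noisy stiffness profile
#'
#' Perturbs the exponential stiffness profile multiplicatively,
#' `S_n -> S_n (1 + noise_sd * gamma_n)` with iid standard Gaussian
#' `gamma_n`, then self-tunes. Average enhancement survives, but the rms
#' profile develops spikes where the perturbed stiffness is locally
#' non-monotonic (the travelling wave is suppressed before resonance and
#' neighbouring hair cells overcompensate).
#'
#' @inheritParams self_tune
#' @param noise_sd relative standard deviation of the stiffness
#'   perturbation (0.01 = 1%).
#' @param seed RNG seed for the perturbation draw (required: the draw is
#'   part of the experiment definition).
#' @return a `"tuning_state"` with extra elements `stiffness_factor` and
#'   `nonmonotonic` (logical per segment: stiffness locally increasing).
#' @export
experiment_stiffness_noise <- function(params, kernel, h0_multiple = 5,
                                       noise_sd = 0.01, seed, ...) {
  if (missing(seed)) stop("`seed` is required")
  set.seed(seed)
  fac <- 1 + noise_sd * stats::rnorm(params$N)
  if (any(fac <= 0))
    stop("stiffness rendered non-positive by extreme noise; rejecting draw")
  pp <- unclass(params)
  pp$stiffness_factor <- NULL
  p2 <- do.call(cochlea_params, c(pp, list(stiffness_factor = fac)))
  ts <- self_tune(p2, kernel, h0_multiple = h0_multiple, ...)
  S <- bm_stiffness(p2, cochlea_grid(p2)$x)
  ts$stiffness_factor <- fac
  ts$nonmonotonic <- c(diff(S) > 0, FALSE)
  ts
}
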