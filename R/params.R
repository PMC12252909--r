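#' Physical parameters of the cochlea model
#'
#' Constructs the full set of physical constants of the cochlear
#' transmission-line model, together with the discretization size `N`.
#' Defaults are the standard human-cochlea values used throughout the
#' package (SI units; angular frequencies in rad/s).
#'
#' The model describes two fluid-filled compartments separated by the
#' basilar membrane (BM), driven through the oval window (OW) and open at
#' the helicotrema (apex, `x = L`). The BM stiffness per unit mass decays
#' exponentially along the membrane, `S(x) = omega0^2 exp(-2 k x)`, so the
#' local resonant frequency runs from `omega0` at the base down to
#' `omega0 exp(-k L)` (about 2 pi * 166 rad/s) at the apex.
#'
#' @param N number of BM segments (positive integer, at least 2).
#' @param rho fluid density (kg/m^3).
#' @param A_cs average cross-sectional area of one cochlear compartment (m^2).
#' @param A_ow area of the oval window (m^2).
#' @param W_bm average width of the basilar membrane (m).
#' @param xi_ow oval-window damping constant (1/s).
#' @param xi BM damping constant per unit mass (1/s).
#' @param omega_ow oval-window (middle-ear) resonant frequency (rad/s).
#' @param omega0 highest resonant frequency of the BM, at the base (rad/s).
#' @param k stiffness decay coefficient (1/m).
#' @param sigma_ow effective areal density of the oval window (kg/m^2).
#' @param sigma_bm areal density of the basilar membrane (kg/m^2).
#' @param G_me pressure gain of the middle ear (dimensionless).
#' @param L length of the basilar membrane (m).
#' @param stiffness_factor optional length-`N` vector of positive
#'   multiplicative factors applied to the stiffness `S(x_n)` at each grid
#'   node (used for stiffness-perturbation experiments). `NULL` means a
#'   clean exponential profile.
#'
#' @return An object of class `"cochlea_params"` (a named list).
#' @examples
#' p <- cochlea_params(N = 100)
#' resonant_frequency_passive(p, 0) / (2 * pi)   # 20800 Hz at the base
#' resonant_frequency_passive(p, p$L) / (2 * pi) # ~166 Hz at the apex
#' @export
cochlea_params <- function(N = 1000L,
                           rho = 1e3,
                           A_cs = 1.1e-6,
                           A_ow = 3.2e-6,
                           W_bm = 2.9e-4,
                           xi_ow = 500,
                           xi = 100,
                           omega_ow = 2 * pi * 1500,
                           omega0 = 2 * pi * 20800,
                           k = 1.38e2,
                           sigma_ow = 18.5,
                           sigma_bm = 5.5e-2,
                           G_me = 21.4,
                           L = 3.5e-2,
                           stiffness_factor = NULL) {
  N <- as.integer(N)
  if (is.na(N) || N < 2L)
    stop("`N` must be an integer >= 2")
  consts <- list(rho = rho, A_cs = A_cs, A_ow = A_ow, W_bm = W_bm,
                 xi_ow = xi_ow, xi = xi, omega_ow = omega_ow,
                 omega0 = omega0, k = k, sigma_ow = sigma_ow,
                 sigma_bm = sigma_bm, G_me = G_me, L = L)
  bad <- names(consts)[!vapply(consts, function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v) && v > 0, logical(1))]
  if (length(bad))
    stop("physical constants must be single positive numbers; offending: ",
         paste(bad, collapse = ", "))
  if (!is.null(stiffness_factor)) {
    stiffness_factor <- as.numeric(stiffness_factor)
    if (length(stiffness_factor) != N)
      stop("`stiffness_factor` must have length N = ", N)
    if (any(!is.finite(stiffness_factor)) || any(stiffness_factor <= 0))
      stop("`stiffness_factor` must be finite and strictly positive ",
           "(a draw rendered the stiffness non-positive)")
  }
  p <- c(consts, list(N = N, stiffness_factor = stiffness_factor))
  class(p) <- "cochlea_params"
  p
}

#' @export
print.cochlea_params <- function(x, ...) {
  cat("<cochlea_params>  N =", x$N, " segments, L =", x$L, "m\n")
  cat(sprintf("  base resonance %0.0f Hz, apex resonance %0.1f Hz, xi = %g 1/s\n",
              x$omega0 / (2 * pi),
              x$omega0 * exp(-x$k * x$L) / (2 * pi), x$xi))
  if (!is.null(x$stiffness_factor))
    cat("  stiffness profile perturbed (multiplicative factors attached)\n")
  invisible(x)
}

#' Spatial grid of the discretized basilar membrane
#'
#' Segment `n` sits at `x_n = L * n / N` for `n = 1..N`, so the last
#' segment lies exactly at the helicotrema.
#'
#' @param params a [cochlea_params()] object.
#' @return list with `x` (positions, m) and `dx` (spacing `L/N`, m).
#' @export
cochlea_grid <- function(params) {
  stopifnot(inherits(params, "cochlea_params"))
  list(x = params$L * seq_len(params$N) / params$N, dx = params$L / params$N)
}

check_position <- function(params, x) {
  if (any(!is.finite(x)) || any(x < -1e-12) || any(x > params$L * (1 + 1e-12)))
    stop("position `x` must lie within [0, L] = [0, ", params$L, "]")
  invisible(x)
}

## Stiffness per unit mass S(x) = omega0^2 e^{-2kx}, optionally carrying the
## node-wise multiplicative perturbation (nearest-node lookup off the grid).
bm_stiffness <- function(params, x) {
  check_position(params, x)
  S <- params$omega0^2 * exp(-2 * params$k * x)
  if (!is.null(params$stiffness_factor)) {
    n <- pmin(pmax(round(x * params$N / params$L), 1L), params$N)
    S <- S * params$stiffness_factor[n]
  }
  S
}

#' Passive resonant frequency of the basilar membrane
#'
#' The local resonance `omega_res^pas(x)` where the stiffness and inertial
#' contributions to the passive impedance cancel. For the clean exponential
#' stiffness profile this is `omega0 * exp(-k x)`.
#'
#' @param params a [cochlea_params()] object.
#' @param x position(s) along the BM in metres, within `[0, L]`.
#' @return angular frequency (rad/s), vectorized over `x`.
#' @export
resonant_frequency_passive <- function(params, x) {
  sqrt(bm_stiffness(params, x))
}

#' Position resonant at a given frequency
#'
#' Inverts the passive resonance map: `x_res = log(omega0 / omega) / k`.
#' The returned position may exceed `L`, in which case no place inside the
#' cochlea resonates at `omega` (the signature of an extended mode).
#'
#' @param params a [cochlea_params()] object.
#' @param omega angular frequency (rad/s), positive.
#' @return position (m), vectorized over `omega`.
#' @export
resonant_position <- function(params, omega) {
  if (any(omega <= 0)) stop("`omega` must be positive")
  log(params$omega0 / omega) / params$k
}

#' Passive acoustic impedance of the basilar membrane
#'
#' `Z_pas(x, omega) = S(x) - omega^2 + i xi omega` with
#' `S(x) = omega0^2 exp(-2 k x)` (units 1/s^2: pressure per unit height per
#' unit areal density). Real `omega` of either sign is accepted;
#' conjugate symmetry `Z(x, -omega) = Conj(Z(x, omega))` reflects the real
#' time-domain dynamics.
#'
#' @param params a [cochlea_params()] object.
#' @param x position(s) in metres, within `[0, L]`.
#' @param omega angular frequency (rad/s), any real value.
#' @return complex impedance, vectorized over `x` and `omega` (recycled).
#' @export
passive_impedance <- function(params, x, omega) {
  bm_stiffness(params, x) - omega^2 + 1i * params$xi * omega
}
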