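#' Hair-cell linear-response kernels
#'
#' Hair cells exert an active pressure on the basilar membrane that depends
#' linearly on past displacement through a causal kernel `g(x, dt)`,
#' scaled by a dimensionless strength `C(x)`:
#' `p_hc(x, t) = sigma_bm C(x) integral g(x, dt) h(x, t - dt) d(dt)`.
#' Four kernel families are supported; rates are tied to the local passive
#' resonance, `r_j(x) = alpha_j * omega_res_pas(x)`:
#'
#' * `single_exp`: `g = theta(dt) xi omega0^2 exp(-r dt)` — the cell
#'   integrates displacement over a time of order `1/r` (e.g. accumulated
#'   calcium driving motors).
#' * `approx_derivative`: difference of two exponentials weighted by
#'   `-r2/r1` so that the zeroth moment vanishes (a static shift in `h`
#'   produces no force); approaches an instantaneous derivative as
#'   `alpha1, alpha2 -> Inf`.
#' * `zero_derivative`: weight `-r2^2/r1^2`, making the *first* moment
#'   vanish, `integral g(dt) dt d(dt) = 0`, equivalently
#'   `d g~/d omega = 0` at `omega = 0` — net friction is then unperturbed
#'   at low frequency regardless of `C`.
#' * `instant_derivative`: the idealized limit `g~ = -i xi omega`,
#'   normalized so `C = 1` cancels the passive friction exactly at all
#'   frequencies; it needs no auxiliary state.
#'
#' Equal rates (`alpha1 == alpha2`) in the two-exponential families are a
#' removable degeneracy: the difference of exponentials vanishes and the
#' family is continued by its analytic (confluent) limit, a
#' `dt * exp(-r dt)` kernel, rescaled to keep the units of `g`.
#'
#' Note a structural symmetry of the two-exponential families: swapping
#' `(alpha1, alpha2)` multiplies `g~` by a negative scalar, so the physical
#' active impedance `C_f * g~` with `C_f` built by [activity_for_fraction()]
#' is invariant under the swap. The sign of the constructed `C_f` follows
#' the sign of `-Im g~` at resonance and can be negative for one ordering;
#' the kernel-plus-strength pair, not `C` alone, is the physical object.
#'
#' @param family one of `"single_exp"`, `"approx_derivative"`,
#'   `"zero_derivative"`, `"instant_derivative"`.
#' @param alpha rate multiplier for `single_exp` (dimensionless, > 0).
#' @param alpha1,alpha2 rate multipliers for the two-exponential families.
#' @return object of class `"hc_kernel"`.
#' @examples
#' ker <- hair_cell_kernel("single_exp", alpha = 2)
#' p <- cochlea_params(N = 100)
#' kernel_transfer(ker, p, x = 0.02, omega = 2 * pi * 500)
#' @export
hair_cell_kernel <- function(family = c("single_exp", "approx_derivative",
                                        "zero_derivative", "instant_derivative"),
                             alpha = NULL, alpha1 = NULL, alpha2 = NULL) {
  family <- match.arg(family)
  k <- list(family = family)
  if (family == "single_exp") {
    if (is.null(alpha) || !is.finite(alpha) || alpha <= 0)
      stop("`single_exp` kernel requires a single positive `alpha`")
    k$alpha <- alpha
  } else if (family %in% c("approx_derivative", "zero_derivative")) {
    if (is.null(alpha1) || is.null(alpha2) ||
        !is.finite(alpha1) || !is.finite(alpha2) || alpha1 <= 0 || alpha2 <= 0)
      stop("two-exponential kernels require positive `alpha1` and `alpha2`")
    k$alpha1 <- alpha1
    k$alpha2 <- alpha2
  }
  class(k) <- "hc_kernel"
  k
}

#' @export
print.hc_kernel <- function(x, ...) {
  pars <- switch(x$family,
    single_exp = sprintf("alpha = %g", x$alpha),
    instant_derivative = "(no rate parameters)",
    sprintf("alpha1 = %g, alpha2 = %g", x$alpha1, x$alpha2))
  cat("<hc_kernel> ", x$family, " ", pars, "\n", sep = "")
  invisible(x)
}

## number of auxiliary state variables per BM segment
kernel_n_aux <- function(kernel) {
  switch(kernel$family,
         single_exp = 1L,
         approx_derivative = 2L,
         zero_derivative = 2L,
         instant_derivative = 0L)
}

kernel_is_confluent <- function(kernel) {
  kernel$family %in% c("approx_derivative", "zero_derivative") &&
    abs(kernel$alpha1 - kernel$alpha2) <=
      1e-9 * max(kernel$alpha1, kernel$alpha2)
}

## weight of the second exponential relative to the first
kernel_w2 <- function(kernel, r1, r2) {
  switch(kernel$family,
         approx_derivative = -r2 / r1,
         zero_derivative = -(r2 / r1)^2,
         stop("kernel has no second exponential"))
}

#' Frequency-domain hair-cell kernel
#'
#' Closed-form Fourier transform `g~(x, omega)` of the time-domain response
#' kernel (convention `g~(omega) = integral exp(-i omega t) g(t) dt`, so
#' `g~(-omega) = Conj(g~(omega))`). Units 1/s^2, matching the impedance.
#'
#' @param kernel a [hair_cell_kernel()].
#' @param params a [cochlea_params()].
#' @param x position(s) (m) in `[0, L]`.
#' @param omega angular frequency (rad/s), any real value.
#' @return complex, vectorized over `x`/`omega` (recycled).
#' @export
kernel_transfer <- function(kernel, params, x, omega) {
  pref <- params$xi * params$omega0^2
  wres <- resonant_frequency_passive(params, x)
  switch(kernel$family,
    instant_derivative = -1i * params$xi * omega + 0 * wres,
    single_exp = {
      r <- kernel$alpha * wres
      pref / (r + 1i * omega)
    },
    {
      if (kernel_is_confluent(kernel)) {
        r <- kernel$alpha1 * wres
        cc <- if (kernel$family == "approx_derivative") 1 else 2
        pref * (r / (r + 1i * omega)^2 - cc / (r + 1i * omega))
      } else {
        r1 <- kernel$alpha1 * wres
        r2 <- kernel$alpha2 * wres
        w2 <- kernel_w2(kernel, r1, r2)
        pref * (1 / (r1 + 1i * omega) + w2 / (r2 + 1i * omega))
      }
    })
}

#' Time-domain hair-cell kernel
#'
#' Evaluates `g(x, dt)` on a grid of time lags. Causality: the kernel is
#' zero for `dt < 0`. Not defined for the `instant_derivative` family,
#' whose kernel is the distributional derivative of a delta function.
#'
#' @inheritParams kernel_transfer
#' @param dt time lag(s) in seconds.
#' @return numeric, vectorized over `dt` (for scalar `x`).
#' @export
kernel_time <- function(kernel, params, x, dt) {
  if (kernel$family == "instant_derivative")
    stop("instant_derivative kernel has no regular time-domain form")
  pref <- params$xi * params$omega0^2
  wres <- resonant_frequency_passive(params, x)
  pos <- as.numeric(dt >= 0)
  if (kernel$family == "single_exp") {
    r <- kernel$alpha * wres
    return(pos * pref * exp(-r * pmax(dt, 0)))
  }
  if (kernel_is_confluent(kernel)) {
    r <- kernel$alpha1 * wres
    cc <- if (kernel$family == "approx_derivative") 1 else 2
    return(pos * pref * exp(-r * pmax(dt, 0)) * (r * pmax(dt, 0) - cc))
  }
  r1 <- kernel$alpha1 * wres
  r2 <- kernel$alpha2 * wres
  w2 <- kernel_w2(kernel, r1, r2)
  pos * pref * (exp(-r1 * pmax(dt, 0)) + w2 * exp(-r2 * pmax(dt, 0)))
}

#' Total acoustic impedance including hair-cell activity
#'
#' `Z(x, omega) = Z_pas(x, omega) + C(x) g~(x, omega)`.
#'
#' @inheritParams kernel_transfer
#' @param C activity strength, scalar or vector recycled against `x`.
#' @return complex impedance (1/s^2).
#' @export
total_impedance <- function(kernel, C, params, x, omega) {
  passive_impedance(params, x, omega) +
    as.numeric(C) * kernel_transfer(kernel, params, x, omega)
}

#' Relative net friction
#'
#' `Xi_net(x, omega) = Im Z(x, omega) / (xi omega)`: effective dissipation
#' in units of the passive friction. `Xi_net = 1` everywhere for a passive
#' cochlea; negative values mean hair cells inject more energy than
#' friction removes at that position and frequency.
#'
#' @inheritParams total_impedance
#' @return dimensionless, vectorized.
#' @export
net_friction <- function(kernel, C, params, x, omega) {
  if (any(omega == 0))
    stop("net friction is undefined at omega = 0")
  Im(total_impedance(kernel, C, params, x, omega)) / (params$xi * omega)
}

## Find the root of f on a bracket grown geometrically around omega_guess.
grow_bracket_root <- function(f, omega_guess, what = "Re Z") {
  lo <- 0.7 * omega_guess
  hi <- 1.3 * omega_guess
  flo <- f(lo)
  fhi <- f(hi)
  grow <- 0L
  while (flo * fhi > 0 && grow < 40L) {
    lo <- lo / 1.35
    hi <- hi * 1.35
    flo <- f(lo)
    fhi <- f(hi)
    grow <- grow + 1L
  }
  if (flo * fhi > 0)
    stop("no sign change of ", what, " found in [",
         format(lo), ", ", format(hi), "] rad/s around ",
         format(omega_guess), "; f(lo) = ", format(flo),
         ", f(hi) = ", format(fhi))
  stats::uniroot(f, c(lo, hi), tol = 1e-10 * omega_guess,
                 f.lower = flo, f.upper = fhi, maxiter = 2000L)$root
}

#' Active resonant frequency
#'
#' Solves `Re Z(x, omega_res) = 0` for the resonance of the full (passive
#' plus active) impedance, bracketed around the passive resonance. With
#' `C = 0`, or with the purely imaginary `instant_derivative` kernel, this
#' equals the passive resonance.
#'
#' @inheritParams total_impedance
#' @return angular frequency (rad/s), vectorized over `x` (with `C`
#'   recycled against `x`).
#' @export
resonant_frequency_active <- function(kernel, C, params, x) {
  C <- rep_len(as.numeric(C), length(x))
  wpas <- resonant_frequency_passive(params, x)
  out <- wpas
  for (i in seq_along(x)) {
    if (C[i] == 0 || kernel$family == "instant_derivative") next
    S <- bm_stiffness(params, x[i])
    f <- function(w) S - w^2 + C[i] * Re(kernel_transfer(kernel, params, x[i], w))
    out[i] <- grow_bracket_root(f, wpas[i])
  }
  out
}

#' Activity profile canceling a fraction of friction at resonance
#'
#' Constructs the strength profile `C_f(x)` such that the net friction on
#' the resonance line is exactly `1 - f`:
#' `C_f(x) = -f xi omega_res(x) / Im g~(x, omega_res(x))`, where the
#' resonance `omega_res` itself solves `Re Z = 0` with the same `C_f` —
#' a circular definition resolved by fixed-point iteration seeded at the
#' passive resonance (converged when the relative change in both
#' `omega_res` and `C` falls below `tol`).
#'
#' @inheritParams kernel_transfer
#' @param f fraction of passive friction canceled at resonance, in
#'   `[0, ~1.05]` (values slightly above 1 are allowed for instability
#'   experiments).
#' @param x positions at which to build the profile; defaults to the grid.
#' @param tol relative fixed-point tolerance.
#' @param max_iter maximum fixed-point iterations.
#' @return an `"activity_profile"`: numeric vector `C` with attributes
#'   `x` (positions), `omega_res` (converged resonances, rad/s) and
#'   `provenance`.
#' @examples
#' p <- cochlea_params(N = 50)
#' ker <- hair_cell_kernel("single_exp", alpha = 2)
#' C99 <- activity_for_fraction(ker, p, f = 0.99)
#' range(net_friction(ker, C99, p, attr(C99, "x"), attr(C99, "omega_res")))
#' @export
activity_for_fraction <- function(kernel, params, f,
                                  x = cochlea_grid(params)$x,
                                  tol = 1e-12, max_iter = 50L) {
  if (!is.finite(f) || f < 0 || f > 1.05)
    stop("`f` must lie in [0, 1.05]")
  wpas <- resonant_frequency_passive(params, x)
  C <- numeric(length(x))
  wres <- wpas
  if (f > 0) {
    for (i in seq_along(x)) {
      S <- bm_stiffness(params, x[i])
      w <- wpas[i]
      Cold <- 0
      for (it in seq_len(max_iter)) {
        gt <- kernel_transfer(kernel, params, x[i], w)
        if (Im(gt) == 0)
          stop("Im g~ vanishes at resonance (x = ", format(x[i]),
               "): the fraction-f construction is singular for this kernel")
        Ci <- -f * params$xi * w / Im(gt)
        wnew <- if (kernel$family == "instant_derivative") w else
          grow_bracket_root(function(v)
            S - v^2 + Ci * Re(kernel_transfer(kernel, params, x[i], v)), w)
        dw <- abs(wnew - w) / w
        dC <- if (Ci == 0) 0 else abs(Ci - Cold) / abs(Ci)
        w <- wnew
        Cold <- Ci
        if (dw < tol && dC < tol) break
      }
      ## one final strength evaluation at the converged resonance, so that
      ## Im Z(x, wres) = (1 - f) xi wres holds to roundoff
      C[i] <- -f * params$xi * w / Im(kernel_transfer(kernel, params, x[i], w))
      wres[i] <- w
    }
  }
  activity_profile(C, x, provenance = sprintf("fraction f = %g", f),
                   omega_res = wres)
}

#' Activity profile container
#'
#' A numeric strength vector tagged with the positions it lives on and a
#' provenance label.
#'
#' @param C numeric strengths.
#' @param x positions (m), same length as `C`.
#' @param provenance character tag (e.g. `"fraction f = 0.99"`,
#'   `"self-tuned"`, `"custom"`).
#' @param omega_res optional per-position resonances (rad/s).
#' @return object of class `"activity_profile"`.
#' @export
activity_profile <- function(C, x, provenance = "custom", omega_res = NULL) {
  C <- as.numeric(C)
  if (length(C) != length(x)) stop("`C` and `x` must have equal length")
  structure(C, x = as.numeric(x), provenance = provenance,
            omega_res = omega_res, class = "activity_profile")
}

#' @export
print.activity_profile <- function(x, ...) {
  cat("<activity_profile> ", length(x), " segments, ",
      attr(x, "provenance"), "\n", sep = "")
  cat(sprintf("  range of C: [%0.4g, %0.4g]\n",
              min(unclass(x)), max(unclass(x))))
  invisible(x)
}
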