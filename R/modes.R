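#' Frequency threshold separating extended from localized modes
#'
#' The resonance of the apex segment (`x = L`): oscillatory modes below it
#' have no resonant place inside the cochlea and are extended
#' (standing-wave-like); modes above it are localized. Resonance means
#' `Re Z = 0` of the *total* impedance, so with active hair cells the
#' threshold includes the activity-induced shift — for the
#' single-exponential kernel the apex shift is `omega_pas * sqrt(1 + f xi
#' r(L) / omega_pas^2)`, about 9% (166 to 181 Hz) at `alpha = 2`,
#' `f = 0.99`, far from negligible. With `C_apex = 0` (or a purely
#' imaginary kernel) this reduces to the passive `omega0 * exp(-k L)`.
#'
#' @param params a [cochlea_params()].
#' @param kernel optional [hair_cell_kernel()]; `NULL` means passive.
#' @param C_apex activity strength at the apex segment.
#' @return angular frequency (rad/s).
#' @export
extended_mode_threshold <- function(params, kernel = NULL, C_apex = 0) {
  if (is.null(kernel) || all(C_apex == 0))
    return(params$omega0 * exp(-params$k * params$L))
  resonant_frequency_active(kernel, C_apex, params, params$L)
}

#' Eigenmodes of the cochlea state space
#'
#' Diagonalizes the Jacobian and classifies the modes. Only one member of
#' each complex-conjugate pair is retained (the one with `Im lambda > 0`);
#' purely real eigenvalues are kept as non-oscillatory modes. Oscillatory
#' modes with frequency at or below the helicotrema resonance
#' [extended_mode_threshold()] are classified `"extended"` (ties count as
#' extended), the rest `"localized"`. Height-block eigenvectors are
#' normalized to unit maximum amplitude with the peak entry real-positive.
#'
#' The classification threshold is the *active* apex resonance computed
#' from the state space's own kernel and apex activity strength (see
#' [extended_mode_threshold()]).
#'
#' @param ss a [build_jacobian()] state space.
#' @param values_only if `TRUE`, skip eigenvectors (much faster; the
#'   returned object then carries no `vectors` matrix).
#' @return object of class `"cochlea_modes"`: a list with `table`
#'   (data.frame: `re`, `im`, `freq_hz`, `class`, `x_pred`), `vectors`
#'   (complex `N x n_modes` height-block eigenvectors, oscillatory and
#'   non-oscillatory alike), `x`, `params`, `n_nonosc`.
#' @examples
#' p <- cochlea_params(N = 120)
#' ker <- hair_cell_kernel("single_exp", alpha = 2)
#' C99 <- activity_for_fraction(ker, p, 0.99)
#' md <- eigenmodes(build_jacobian(p, ker, C99))
#' table(md$table$class)
#' @export
eigenmodes <- function(ss, values_only = FALSE) {
  stopifnot(inherits(ss, "cochlea_state_space"))
  e <- eigen(ss$J, only.values = values_only)
  lam <- e$values
  keep <- Im(lam) >= 0 # one of each conjugate pair + real eigenvalues
  lam <- lam[keep]
  ord <- order(Im(lam), Re(lam))
  lam <- lam[ord]
  thr <- extended_mode_threshold(ss$params, ss$kernel, ss$C[ss$params$N])
  cls <- ifelse(Im(lam) == 0, "non_oscillatory",
                ifelse(Im(lam) <= thr, "extended", "localized"))
  tab <- data.frame(re = Re(lam), im = Im(lam),
                    freq_hz = Im(lam) / (2 * pi), class = cls,
                    x_pred = ifelse(Im(lam) > 0,
                                    log(ss$params$omega0 / pmax(Im(lam), 1e-300)) /
                                      ss$params$k, NA_real_))
  vectors <- NULL
  if (!values_only) {
    V <- e$vectors[ss$index_map$h, keep, drop = FALSE][, ord, drop = FALSE]
    for (j in seq_len(ncol(V))) {
      pk <- which.max(abs(V[, j]))
      if (abs(V[pk, j]) > 0)
        V[, j] <- V[, j] / V[pk, j] * abs(V[pk, j]) / max(abs(V[, j]))
    }
    vectors <- V
  }
  structure(list(table = tab, vectors = vectors, x = ss$x,
                 params = ss$params,
                 n_nonosc = sum(cls == "non_oscillatory")),
            class = "cochlea_modes")
}

#' @export
print.cochlea_modes <- function(x, ...) {
  n <- table(factor(x$table$class,
                    c("localized", "extended", "non_oscillatory")))
  cat("<cochlea_modes> ", nrow(x$table), " modes: ",
      n[["localized"]], " localized, ", n[["extended"]], " extended, ",
      n[["non_oscillatory"]], " non-oscillatory\n", sep = "")
  cat(sprintf("  max Re lambda = %0.4g 1/s\n", max(x$table$re)))
  invisible(x)
}

#' Count extended modes
#'
#' Number of oscillatory eigenvalues with `0 < Im lambda <=`
#' [extended_mode_threshold()].
#'
#' @param modes a [eigenmodes()] result (or a state space, which is
#'   diagonalized with `values_only = TRUE`).
#' @return integer count.
#' @export
count_extended_modes <- function(modes) {
  if (inherits(modes, "cochlea_state_space"))
    modes <- eigenmodes(modes, values_only = TRUE)
  sum(modes$table$class == "extended")
}

#' Extended-mode count as a function of discretization size
#'
#' Rebuilds the model at each `N` (with the activity profile reconstructed
#' for that grid) and counts extended modes. The count plateaus at its
#' continuum value once `N` resolves the standing waves; only very coarse
#' grids miss modes.
#'
#' @param params a [cochlea_params()]; its `N` is overridden per entry.
#' @param kernel a [hair_cell_kernel()].
#' @param f fraction of friction canceled at resonance (activity rebuilt
#'   per grid via [activity_for_fraction()]); `f = 0` for passive.
#' @param N_list ascending integer vector of grid sizes.
#' @return data.frame with columns `N` and `n_extended`.
#' @export
count_extended_vs_N <- function(params, kernel, f, N_list) {
  N_list <- as.integer(N_list)
  if (is.unsorted(N_list)) stop("`N_list` must be ascending")
  counts <- vapply(N_list, function(N) {
    p <- do.call(cochlea_params,
                 c(list(N = N), unclass(params)[setdiff(names(unclass(params)),
                                                        c("N", "stiffness_factor"))]))
    C <- if (f > 0) activity_for_fraction(kernel, p, f) else 0
    count_extended_modes(build_jacobian(p, kernel, C))
  }, integer(1))
  data.frame(N = N_list, n_extended = counts)
}

#' Uncoupled-oscillator reference spectrum
#'
#' Eigenvalues of each BM segment treated as an isolated oscillator with
#' the same stiffness, friction and active force: the roots of
#' `Z(x_n, omega = -i lambda) = 0`, obtained per segment by clearing the
#' kernel denominators and solving the resulting polynomial in `lambda`
#' (quadratic for passive/instantaneous kernels, cubic for `single_exp`,
#' quartic for the two-exponential families). The localized modes of the
#' full system approach these roots as the grid is refined or as friction
#' cancellation approaches completion.
#'
#' @inheritParams build_jacobian
#' @return data.frame with `x`, `lambda` (complex oscillatory root with
#'   `Im > 0`, `NA` where the segment has no oscillatory root).
#' @export
uncoupled_spectrum <- function(params, kernel, C = 0) {
  g <- cochlea_grid(params)
  x <- g$x
  N <- params$N
  C <- rep_len(as.numeric(C), N)
  S <- bm_stiffness(params, x)
  xi <- params$xi
  pref <- xi * params$omega0^2
  lam <- rep(NA_complex_, N)
  for (n in seq_len(N)) {
    wres <- sqrt(S[n])
    ## polynomial coefficients, constant term first, in s where lambda = s
    base <- c(S[n], xi, 1) # S + xi s + s^2
    co <- switch(kernel$family,
      instant_derivative = c(S[n], xi * (1 - C[n]), 1),
      single_exp = {
        r <- kernel$alpha * wres
        ## (S + xi s + s^2)(r + s) + C pref
        c(conv_poly(base, c(r, 1)), 0)[1:4] + c(C[n] * pref, 0, 0, 0)
      },
      {
        if (kernel_is_confluent(kernel)) {
          r <- kernel$alpha1 * wres
          cc <- if (kernel$family == "approx_derivative") 1 else 2
          ## (S + xi s + s^2)(r + s)^2 + C pref (r - cc (r + s))
          conv_poly(base, conv_poly(c(r, 1), c(r, 1))) +
            C[n] * pref * c(r - cc * r, -cc, 0, 0, 0)
        } else {
          r1 <- kernel$alpha1 * wres
          r2 <- kernel$alpha2 * wres
          w2 <- kernel_w2(kernel, r1, r2)
          ## (S + xi s + s^2)(r1 + s)(r2 + s) + C pref ((r2+s) + w2 (r1+s))
          conv_poly(base, conv_poly(c(r1, 1), c(r2, 1))) +
            C[n] * pref * c(r2 + w2 * r1, 1 + w2, 0, 0, 0)
        }
      })
    rt <- polyroot(co)
    osc <- rt[Im(rt) > 1e-9 * Mod(rt)]
    if (length(osc)) {
      ## oscillatory root continuously connected to the passive oscillator
      lam[n] <- osc[which.min(abs(Mod(osc) - wres))]
    }
  }
  data.frame(x = x, lambda = lam)
}

## polynomial product, coefficients in increasing-power order
conv_poly <- function(p, q) {
  out <- numeric(length(p) + length(q) - 1L)
  for (i in seq_along(p)) out[i + seq_along(q) - 1L] <-
      out[i + seq_along(q) - 1L] + p[i] * q
  out
}

#' Peak position of a localized mode
#'
#' Returns the position of maximum height amplitude of the mode's
#' eigenvector, the position predicted from its frequency through the
#' resonance map `log(omega0 / Im lambda) / k`, and their discrepancy.
#'
#' @param modes a [eigenmodes()] result with eigenvectors.
#' @param j mode index (row of `modes$table`); must be localized.
#' @return list with `x_peak`, `x_pred`, `discrepancy` (m).
#' @export
peak_position <- function(modes, j) {
  stopifnot(inherits(modes, "cochlea_modes"))
  if (is.null(modes$vectors)) stop("modes were computed without eigenvectors")
  if (modes$table$class[j] != "localized")
    stop("mode ", j, " is ", modes$table$class[j],
         "; peak position is only meaningful for localized modes")
  v <- abs(modes$vectors[, j])
  x_peak <- modes$x[which.max(v)]
  x_pred <- modes$table$x_pred[j]
  list(x_peak = x_peak, x_pred = x_pred,
       discrepancy = abs(x_peak - x_pred))
}

#' Zero crossings of an extended mode
#'
#' Counts sign changes of the real part of the height eigenvector, at the
#' overall complex phase maximizing the real energy `sum(Re(v)^2)` (the
#' standing-wave phase). The extended modes form a ladder: the lowest has
#' no crossings, and each successive one adds one crossing.
#'
#' @inheritParams peak_position
#' @return integer number of sign changes.
#' @export
zero_crossings <- function(modes, j) {
  stopifnot(inherits(modes, "cochlea_modes"))
  if (is.null(modes$vectors)) stop("modes were computed without eigenvectors")
  v <- modes$vectors[, j]
  ## phase phi maximizing sum Re(e^{i phi} v)^2: 2 phi = -Arg(sum v^2)
  phi <- -Arg(sum(v^2)) / 2
  w <- Re(exp(1i * phi) * v)
  w[abs(w) < 1e-9 * max(abs(w))] <- 0
  s <- sign(w[w != 0])
  sum(diff(s) != 0)
}
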