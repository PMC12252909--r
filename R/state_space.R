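#' Assemble the first-order state-space Jacobian of the discretized cochlea
#'
#' Discretizes the fluid-coupled basilar-membrane dynamics into `N`
#' segments at `x_n = L n / N` and writes the model as `dX/dt = J X + B P_ec`.
#' The state `X` concatenates the heights `h_n`, their velocities, any
#' auxiliary kernel states `q_n` (one per segment for `single_exp`, two for
#' the two-exponential families, none for `instant_derivative`), and the
#' oval-window displacement and velocity.
#'
#' The pressure at node `n` is
#' `p_n = sigma_bm (S_n h_n + xi dh_n + d2h_n) + p_hc,n`, and the wave
#' equation `(2 rho W_bm / A_cs) d2h_n = (p_{n+1} - 2 p_n + p_{n-1}) / dx^2`
#' is closed with a ghost node at the base implementing the oval-window flux
#' condition `dp/dx(0) = 2 rho (A_ow / A_cs) d2d_ow`, and with `p = 0` at
#' the node beyond `x_N` (the helicotrema), which keeps all `N` heights
#' dynamical. Because the acceleration `d2h` appears inside `p`, assembly
#' solves one linear system for the acceleration coupling: a mass matrix
#' over `(d2h_1..d2h_N, d2d_ow)` is factorized once at build time.
#'
#' @param params a [cochlea_params()].
#' @param kernel a [hair_cell_kernel()].
#' @param C activity strengths: scalar or length-`N` vector (an
#'   [activity_profile()] built on the grid works directly).
#' @return object of class `"cochlea_state_space"` with elements `J` (real
#'   `D x D` Jacobian), `B` (input vector mapping ear-canal pressure to
#'   state derivatives), `index_map` (named list of integer state indices:
#'   `h`, `h_dot`, `q1`, `q2`, `d_ow`, `d_ow_dot`), `x`, `dx`, `params`,
#'   `kernel`, `C`.
#' @examples
#' p <- cochlea_params(N = 40)
#' ker <- hair_cell_kernel("single_exp", alpha = 2)
#' ss <- build_jacobian(p, ker, 0)      # passive cochlea
#' nrow(ss$J)                            # 3 * 40 + 2 states
#' @export
build_jacobian <- function(params, kernel, C = 0) {
  stopifnot(inherits(params, "cochlea_params"), inherits(kernel, "hc_kernel"))
  N <- params$N
  g <- cochlea_grid(params)
  x <- g$x
  dx <- g$dx
  C <- rep_len(as.numeric(C), N)

  m_aux <- kernel_n_aux(kernel)
  D <- (2L + m_aux) * N + 2L
  ih <- seq_len(N)
  ihd <- N + seq_len(N)
  iq1 <- if (m_aux >= 1L) 2L * N + seq_len(N) else integer(0)
  iq2 <- if (m_aux >= 2L) 3L * N + seq_len(N) else integer(0)
  iow <- (2L + m_aux) * N + 1L
  iowd <- iow + 1L
  index_map <- list(h = ih, h_dot = ihd, q1 = iq1, q2 = iq2,
                    d_ow = iow, d_ow_dot = iowd)

  S <- bm_stiffness(params, x)
  a_fl <- 2 * params$rho * params$W_bm / params$A_cs # fluid inertia coupling
  b <- params$sigma_bm
  c_ow <- 2 * params$rho * params$A_ow / params$A_cs # base ghost-node coupling
  mu <- c_ow * dx / params$sigma_ow

  ## mass matrix over accelerations (d2h_1..d2h_N, d2d_ow)
  M <- matrix(0, N + 1L, N + 1L)
  ## modified discrete Laplacian acting on node pressures:
  ## row 1 uses the ghost closure (p_2 - p_1)/dx^2, row N has p_{N+1} = 0
  Lap <- matrix(0, N, N)
  for (n in seq_len(N)) {
    if (n > 1L) Lap[n, n - 1L] <- 1 / dx^2
    Lap[n, n] <- -2 / dx^2
    if (n < N) Lap[n, n + 1L] <- 1 / dx^2
  }
  Lap[1L, 1L] <- -1 / dx^2
  M[seq_len(N), seq_len(N)] <- -b * Lap
  diag(M)[seq_len(N)] <- diag(M)[seq_len(N)] + a_fl
  M[1L, N + 1L] <- c_ow / dx
  M[N + 1L, 1L] <- -b / params$sigma_ow
  M[N + 1L, N + 1L] <- 1 + mu

  kap <- kappa(M, exact = FALSE)
  if (!is.finite(kap) || kap > 1e14)
    stop("acceleration mass matrix is numerically singular ",
         "(condition number estimate ", format(kap), ")")

  ## static (non-acceleration) part of the node pressure:
  ##   pi_n = b (S_n h_n + xi_eff_n dh_n) + p_hc,n(q)
  xi_eff <- rep(params$xi, N)
  if (kernel$family == "instant_derivative")
    xi_eff <- params$xi * (1 - C)
  hc_pref <- b * C * params$xi * params$omega0^2

  ## K maps the state to the forcing of (d2h, d2d_ow); one column block per
  ## state block, built by applying the Laplacian to the pi coefficients
  K <- matrix(0, N + 1L, D)
  K[seq_len(N), ih] <- Lap %*% diag(b * S, N)
  K[seq_len(N), ihd] <- Lap %*% diag(b * xi_eff, N)
  confluent <- kernel_is_confluent(kernel)
  if (m_aux >= 1L) {
    if (kernel$family == "single_exp") {
      wq1 <- hc_pref
      wq2 <- NULL
    } else if (confluent) {
      r <- kernel$alpha1 * sqrt(S)
      cc <- if (kernel$family == "approx_derivative") 1 else 2
      wq1 <- -cc * hc_pref
      wq2 <- r * hc_pref
    } else {
      r1 <- kernel$alpha1 * sqrt(S)
      r2 <- kernel$alpha2 * sqrt(S)
      wq1 <- hc_pref
      wq2 <- hc_pref * kernel_w2(kernel, r1, r2)
    }
    K[seq_len(N), iq1] <- Lap %*% diag(wq1, N)
    if (m_aux >= 2L) K[seq_len(N), iq2] <- Lap %*% diag(wq2, N)
  }
  ## oval-window row: d2d_ow = -xi_ow dd - omega_ow^2 d + (pi_1 + Gme Pec)/sigma_ow
  K[N + 1L, ih[1L]] <- b * S[1L] / params$sigma_ow
  K[N + 1L, ihd[1L]] <- b * xi_eff[1L] / params$sigma_ow
  if (m_aux >= 1L) K[N + 1L, iq1[1L]] <- wq1[1L] / params$sigma_ow
  if (m_aux >= 2L) K[N + 1L, iq2[1L]] <- wq2[1L] / params$sigma_ow
  K[N + 1L, iow] <- -params$omega_ow^2
  K[N + 1L, iowd] <- -params$xi_ow

  U <- solve(M, K)
  Bred <- solve(M, c(rep(0, N), params$G_me / params$sigma_ow))

  J <- matrix(0, D, D)
  J[cbind(ih, ihd)] <- 1                     # dh/dt = h_dot
  J[ihd, ] <- U[seq_len(N), ]                # accelerations
  if (m_aux >= 1L) {
    if (kernel$family == "single_exp") {
      r1 <- kernel$alpha * sqrt(S)
      J[cbind(iq1, iq1)] <- -r1
      J[cbind(iq1, ih)] <- 1
    } else if (confluent) {
      r <- kernel$alpha1 * sqrt(S)
      J[cbind(iq1, iq1)] <- -r
      J[cbind(iq1, ih)] <- 1
      J[cbind(iq2, iq2)] <- -r
      J[cbind(iq2, iq1)] <- 1
    } else {
      r1 <- kernel$alpha1 * sqrt(S)
      r2 <- kernel$alpha2 * sqrt(S)
      J[cbind(iq1, iq1)] <- -r1
      J[cbind(iq1, ih)] <- 1
      J[cbind(iq2, iq2)] <- -r2
      J[cbind(iq2, ih)] <- 1
    }
  }
  J[iow, iowd] <- 1
  J[iowd, ] <- U[N + 1L, ]

  B <- numeric(D)
  B[ihd] <- Bred[seq_len(N)]
  B[iowd] <- Bred[N + 1L]

  structure(list(J = J, B = B, index_map = index_map, x = x, dx = dx,
                 params = params, kernel = kernel, C = C),
            class = "cochlea_state_space")
}

#' @export
print.cochlea_state_space <- function(x, ...) {
  cat("<cochlea_state_space> ", nrow(x$J), " states (N = ", x$params$N,
      " segments, kernel ", x$kernel$family, ")\n", sep = "")
  invisible(x)
}

#' Frequency-domain operator for the driven cochlea
#'
#' Assembles and solves the banded complex linear system for the
#' steady-state height profile `h~(x)` under a pure tone of angular
#' frequency `omega` entering through the ear canal with complex pressure
#' amplitude `P_ec`. The unknowns are `(h~_1 .. h~_N, d~_ow)`, and the node
#' pressure is expressed through the total impedance,
#' `p~_n = sigma_bm Z(x_n, omega) h~_n`. Boundary handling matches
#' [build_jacobian()] exactly (ghost node at the base, `p = 0` beyond the
#' apex node), so the solution equals the steady state of the time-domain
#' system.
#'
#' @inheritParams build_jacobian
#' @param omega drive angular frequency (rad/s), positive.
#' @param P_ec complex ear-canal pressure amplitude (Pa).
#' @return list with `x`, `h` (complex heights), `d_ow` (complex
#'   oval-window displacement), `omega`, `P_ec`.
#' @export
frequency_operator <- function(params, kernel, C, omega, P_ec = 1) {
  stopifnot(inherits(params, "cochlea_params"), inherits(kernel, "hc_kernel"))
  if (!is.finite(omega) || omega <= 0) stop("`omega` must be positive")
  N <- params$N
  g <- cochlea_grid(params)
  x <- g$x
  dx <- g$dx
  C <- rep_len(as.numeric(C), N)

  a_fl <- 2 * params$rho * params$W_bm / params$A_cs
  b <- params$sigma_bm
  c_ow <- 2 * params$rho * params$A_ow / params$A_cs
  Z <- total_impedance(kernel, C, params, x, omega)

  A <- matrix(0 + 0i, N + 1L, N + 1L)
  zp <- b * Z # pressure per unit height
  for (n in seq_len(N)) {
    if (n > 1L) A[n, n - 1L] <- zp[n - 1L] / dx^2
    A[n, n] <- (if (n == 1L) -1 else -2) * zp[n] / dx^2 + a_fl * omega^2
    if (n < N) A[n, n + 1L] <- zp[n + 1L] / dx^2
  }
  A[1L, N + 1L] <- c_ow * omega^2 / dx
  A[N + 1L, 1L] <- -zp[1L] / params$sigma_ow
  A[N + 1L, N + 1L] <- -omega^2 + 1i * params$xi_ow * omega +
    params$omega_ow^2 - dx * c_ow * omega^2 / params$sigma_ow

  rhs <- c(rep(0 + 0i, N), params$G_me * P_ec / params$sigma_ow)
  sol <- solve(A, rhs)
  list(x = x, h = sol[seq_len(N)], d_ow = sol[N + 1L],
       omega = omega, P_ec = P_ec)
}

## Steady-state complex response through the time-domain Jacobian:
## X = (i omega I - J)^{-1} B P_ec. Used to cross-validate the
## frequency-domain operator against the state-space assembly.
statespace_frequency_response <- function(ss, omega, P_ec = 1) {
  D <- nrow(ss$J)
  Xc <- solve(diag(1i * omega, D) - ss$J, ss$B * P_ec, tol = 0)
  list(x = ss$x, h = Xc[ss$index_map$h], d_ow = Xc[ss$index_map$d_ow],
       omega = omega, P_ec = P_ec)
}
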