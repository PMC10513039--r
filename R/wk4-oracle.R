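# Third-order scalar formulation of the modified Windkessel model.
#
# Eliminating q and p_c from the first-order system yields a single ODE in
# the peripheral pressure p (state y = (p, p', p'')):
#   p''' + p''/(R C2) + p' (1/(L C1) + 1/(L C2)) + p/(L R C1 C2)
#        = q_in/(L C1 C2)
# with C1 evaluated at the reconstructed central pressure
#   p_c = L C2 (p'' + p'/(R C2)) + p.
# This plain-R Dormand-Prince integrator is intentionally kept independent
# of the compiled first-order route; the two must agree within 0.5 mmHg
# pointwise (cross-formulation contract), which the test suite asserts.

qin_eval <- function(pars, t_abs, t0) {
  t <- t_abs - t0
  aTs <- pars$alpha * pars$Ts
  q <- if (t < 0 || t > pars$T) 0
  else if (t <= aTs) pars$q0 * sin(pi * t / (2 * aTs))
  else if (t <= pars$Ts) pars$q0 * cos(pi * (t - aTs) / (4 * aTs))
  else 0
  if (length(pars$mini_t0)) {
    hit <- t_abs >= pars$mini_t0 & t_abs < pars$mini_t1
    if (any(hit)) q <- q * prod(pars$mini_factor[hit])
  }
  q
}

rhs_p3 <- function(pars, t, y, t0) {
  p <- y[1]; dp <- y[2]; d2p <- y[3]
  pc <- pars$L * pars$C2 * (d2p + dp / (pars$R * pars$C2)) + p
  z <- (pc - pars$P0) / pars$P1
  C1 <- pars$Am * pars$l / (pi * pars$P1 * (1 + z^2))
  qin <- qin_eval(pars, t, t0)
  d3p <- qin / (pars$L * C1 * pars$C2) -
    d2p / (pars$R * pars$C2) -
    dp * (1 / (pars$L * C1) + 1 / (pars$L * pars$C2)) -
    p / (pars$L * pars$R * C1 * pars$C2)
  c(dp, d2p, d3p)
}

# Dormand-Prince 5(4) tableau (shared by the R-side integrator)
.dp_A <- rbind(
  c(1 / 5, 0, 0, 0, 0, 0),
  c(3 / 40, 9 / 40, 0, 0, 0, 0),
  c(44 / 45, -56 / 15, 32 / 9, 0, 0, 0),
  c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729, 0, 0),
  c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656, 0),
  c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84))
.dp_c <- c(1 / 5, 3 / 10, 4 / 5, 8 / 9, 1, 1)
.dp_b5 <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0)
.dp_b4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200,
            187 / 2100, 1 / 40)

# integrate y' = f(t, y) from t to t_end adaptively; returns list(y, h)
rk45_step_to <- function(f, t, t_end, y, h, rtol, atol, beat_index) {
  while (t < t_end - 1e-12) {
    h <- min(h, t_end - t, 0.05)
    h <- max(h, 1e-12)
    k <- matrix(0, 7, length(y))
    k[1, ] <- f(t, y)
    for (s in 1:6) {
      ys <- y + h * drop(.dp_A[s, seq_len(s), drop = FALSE] %*%
                           k[seq_len(s), , drop = FALSE])
      k[s + 1, ] <- f(t + .dp_c[s] * h, ys)
    }
    y5 <- y + h * drop(.dp_b5 %*% k)
    y4 <- y + h * drop(.dp_b4 %*% k)
    sc <- atol + rtol * pmax(abs(y), abs(y5))
    err <- sqrt(mean(((y5 - y4) / sc)^2))
    if (!is.finite(err))
      stop(sprintf("non-finite state during integration of beat %d",
                   beat_index))
    if (err <= 1) {
      t <- t + h
      y <- y5
    }
    h <- h * min(5, max(0.2, if (err > 0) 0.9 * err^-0.2 else 5))
  }
  list(y = y, h = h)
}

# R-side analogue of wk4_integrate_beat() for the third-order formulation.
# state0 and the returned state are the *physical* state (q, p_c, p_p) so
# that continuity across beats with changing R matches the first-order
# route; the (p, p', p'') coordinates are internal (they depend on R).
wk4_integrate_beat_p3 <- function(state0, pars, t0, dt_out, rtol, atol,
                                  beat_index) {
  keep <- pars$mini_t1 > t0 - 1e-12 & pars$mini_t0 < t0 + pars$T + 1e-12
  pars$mini_t0 <- pars$mini_t0[keep]
  pars$mini_t1 <- pars$mini_t1[keep]
  pars$mini_factor <- pars$mini_factor[keep]

  k0 <- ceiling(t0 / dt_out - 1e-9)
  k1 <- ceiling((t0 + pars$T) / dt_out - 1e-9)  # exclusive
  out_t <- (seq_len(k1 - k0) - 1 + k0) * dt_out
  brk <- sort(unique(c(out_t, t0 + pars$alpha * pars$Ts, t0 + pars$Ts,
                       pmax(pars$mini_t0, t0),
                       pmin(pars$mini_t1, t0 + pars$T), t0 + pars$T)))
  f <- function(t, y) rhs_p3(pars, t, y, t0)
  # physical (q, p_c, p_p) -> (p, p', p'')
  q0s <- state0[1]; pc0 <- state0[2]; pp0 <- state0[3]
  dp0 <- q0s / pars$C2 - pp0 / (pars$R * pars$C2)
  d2p0 <- (pc0 - pp0) / (pars$L * pars$C2) - dp0 / (pars$R * pars$C2)
  y <- c(pp0, dp0, d2p0)
  t <- t0
  h <- dt_out / 4
  n_out <- length(out_t)
  P <- Pc <- Q <- C1v <- Qin <- numeric(n_out)
  io <- 1L
  for (te in brk) {
    if (te > t + 1e-12) {
      st <- rk45_step_to(f, t, te, y, h, rtol, atol, beat_index)
      y <- st$y
      h <- st$h
      t <- te
    }
    if (io <= n_out && abs(te - out_t[io]) < 1e-9) {
      pc <- pars$L * pars$C2 * (y[3] + y[2] / (pars$R * pars$C2)) + y[1]
      z <- (pc - pars$P0) / pars$P1
      P[io] <- y[1]
      Pc[io] <- pc
      Q[io] <- pars$C2 * y[2] + y[1] / pars$R
      C1v[io] <- pars$Am * pars$l / (pi * pars$P1 * (1 + z^2))
      Qin[io] <- qin_eval(pars, te, t0)
      io <- io + 1L
    }
  }
  if (!all(is.finite(y)))
    stop(sprintf("non-finite state at end of beat %d", beat_index))
  # back to physical (q, p_c, p_p)
  q_end <- pars$C2 * y[2] + y[1] / pars$R
  pc_end <- pars$L * pars$C2 * (y[3] + y[2] / (pars$R * pars$C2)) + y[1]
  list(time = out_t, q = Q, p_c = Pc, p_p = P, c1 = C1v, q_in = Qin,
       state = c(q_end, pc_end, y[1]))
}
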