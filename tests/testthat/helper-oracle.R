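# Brute-force reference integrator: fixed-step classical RK4 with linear
# interpolation of the stored intracellular history for the delayed term.
# Deliberately independent of the package's adaptive method-of-steps
# integrator (different order, step control, and history interpolation);
# used as the numerical oracle for trajectory comparisons.
#
# Integrates dI/dt = prod - (beta+gamma) I(t-tau) + eps X
#            dX/dt = beta I(t-tau) - (delta+eps) X
# from t = 0 to t_end starting at (I0, X0), with constant pre-history pre_I
# for t <= 0. `production`: TRUE for the production-on phase, FALSE for a
# chase with production 0. Requires tau = 0 or tau >= 2*h.
oracle_rk4 <- function(p, I0, X0, t_end, pre_I = 0, production = TRUE,
                       h = 1 / 1200) {
  n <- round(t_end / h)
  I <- numeric(n + 1)
  X <- numeric(n + 1)
  I[1] <- I0
  X[1] <- X0
  tau <- p$tau
  lag <- tau / h
  if (tau > 0 && lag < 2) stop("oracle requires tau >= 2*h")
  a <- if (production) p$alpha else 0
  bg <- p$beta + p$gamma
  de <- p$delta + p$epsilon
  b <- p$beta
  eps <- p$epsilon
  # delayed I at fractional step position `pos` (0-based); linear interp
  Id <- function(pos) {
    if (pos <= 0) return(pre_I)
    j <- floor(pos)
    w <- pos - j
    I[j + 1] * (1 - w) + I[j + 2] * w
  }
  for (k in seq_len(n)) {
    pos <- k - 1
    i0 <- I[k]; x0 <- X[k]
    d1 <- if (tau > 0) Id(pos - lag) else i0
    k1I <- a - bg * d1 + eps * x0;            k1X <- b * d1 - de * x0
    i1 <- i0 + h / 2 * k1I; x1 <- x0 + h / 2 * k1X
    d2 <- if (tau > 0) Id(pos + 0.5 - lag) else i1
    k2I <- a - bg * d2 + eps * x1;            k2X <- b * d2 - de * x1
    i2 <- i0 + h / 2 * k2I; x2 <- x0 + h / 2 * k2X
    d3 <- if (tau > 0) Id(pos + 0.5 - lag) else i2
    k3I <- a - bg * d3 + eps * x2;            k3X <- b * d3 - de * x2
    i3 <- i0 + h * k3I; x3 <- x0 + h * k3X
    d4 <- if (tau > 0) Id(pos + 1 - lag) else i3
    k4I <- a - bg * d4 + eps * x3;            k4X <- b * d4 - de * x3
    I[k + 1] <- i0 + h / 6 * (k1I + 2 * k2I + 2 * k3I + k4I)
    X[k + 1] <- x0 + h / 6 * (k1X + 2 * k2X + 2 * k3X + k4X)
  }
  list(times = h * (0:n), I = I, X = X)
}

# values of an oracle solution at whole-minute times; the oracle step must
# divide one minute exactly so grid times are hit, not approximated
oracle_at_minutes <- function(sol, t_end) {
  h <- sol$times[2] - sol$times[1]
  per_min <- 1 / (60 * h)
  stopifnot(abs(per_min - round(per_min)) < 1e-9)
  minutes <- seq(0, round(t_end * 60)) / 60
  idx <- round(minutes * 60 * round(per_min)) + 1
  list(times = minutes, I = sol$I[idx], X = sol$X[idx])
}

# pointwise relative deviation, floored at a fraction of the trajectory max
rel_dev <- function(a, b, floor_frac = 1e-3) {
  scale <- pmax(abs(b), floor_frac * max(abs(b)))
  max(abs(a - b) / scale)
}
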