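# Independent oracles used across the suite.

# Dense matrix of the 5-point zero-flux Laplacian on an nr x nc grid
# (column-major flattening, matching as.vector on R matrices).
dense_neumann_laplacian <- function(nr, nc, dx) {
  n <- nr * nc
  L <- matrix(0, n, n)
  idx <- function(i, j) (j - 1L) * nr + i
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      v <- idx(i, j)
      nb <- c(if (i > 1) idx(i - 1, j), if (i < nr) idx(i + 1, j),
              if (j > 1) idx(i, j - 1), if (j < nc) idx(i, j + 1))
      L[v, nb] <- L[v, nb] + 1
      L[v, v] <- -length(nb)
    }
  }
  L / dx^2
}

# largest real part among the eigenvalues of a 2x2 matrix, via eigen()
eig_lambda_max <- function(m) max(Re(eigen(m, only.values = TRUE)$values))

# frozen activator-inhibitor reaction terms (scalar)
ah_reaction <- function(A, H, S, Y, p) {
  c(f = p[["c"]] * A^2 * S / H - p[["mu"]] * A +
        (p[["rho_A"]] + p[["delta_A"]]) * Y,
    g = p[["c"]] * A^2 * S - p[["nu"]] * H +
        (p[["rho_H"]] + p[["delta_H"]]) * Y)
}

# central finite differences of the frozen reaction terms
fd_ah_jacobian <- function(A, H, S, Y, p, eps = 1e-6) {
  dA <- eps * max(1, abs(A)); dH <- eps * max(1, abs(H))
  fp <- ah_reaction(A + dA, H, S, Y, p); fm <- ah_reaction(A - dA, H, S, Y, p)
  gp <- ah_reaction(A, H + dH, S, Y, p); gm <- ah_reaction(A, H - dH, S, Y, p)
  list(f_A = (fp["f"] - fm["f"]) / (2 * dA),
       g_A = (fp["g"] - fm["g"]) / (2 * dA),
       f_H = (gp["f"] - gm["f"]) / (2 * dH),
       g_H = (gp["g"] - gm["g"]) / (2 * dH))
}

# brute-force steady state of the frozen subsystem: dense scan of the
# substituted activator equation plus local uniroot refinement
bruteforce_ah_steady <- function(S, Y, p, a_max = 100, n = 200000) {
  src_A <- (p[["rho_A"]] + p[["delta_A"]]) * Y
  src_H <- (p[["rho_H"]] + p[["delta_H"]]) * Y
  g <- function(A) {
    H <- (p[["c"]] * A^2 * S + src_H) / p[["nu"]]
    if (H <= 0) return(-p[["mu"]] * A + src_A)
    p[["c"]] * A^2 * S / H - p[["mu"]] * A + src_A
  }
  a <- exp(seq(log(1e-8), log(a_max), length.out = n))
  gv <- vapply(a, g, numeric(1))
  flips <- which(sign(gv[-1]) * sign(gv[-n]) < 0)
  roots <- vapply(flips, function(i)
    stats::uniroot(g, c(a[i], a[i + 1]), tol = 1e-14)$root, numeric(1))
  sort(roots)
}

# explicit one-step oracle assembled in R from the module surface
euler_step_oracle <- function(state, params, grid, dt, h_floor = 1e-6) {
  r <- reaction_rhs(state, params, h_floor = h_floor)
  p <- stats::setNames(as.numeric(params), names(params))
  A <- state$A + dt * (r$dA + p[["D_A"]] * rd_laplacian(state$A, grid))
  H <- state$H + dt * (r$dH + p[["D_H"]] * rd_laplacian(state$H, grid))
  S <- state$S + dt * (r$dS + p[["D_S"]] * rd_laplacian(state$S, grid))
  Y <- state$Y + dt * r$dY
  rd_state(pmax(A, 0), pmax(H, 0), pmax(S, 0), pmax(Y, 0),
           t = state$t + dt)
}
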