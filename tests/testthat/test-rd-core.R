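test_that("reaction terms match hand-evaluated values", {
  g <- rd_grid(4, 4)
  p <- rd_preset("spine")   # c = 0.002, mu = 0.16, rho_A + delta_A = 0.02

  # production terms vanish where A = 0 and Y = 0
  st <- uniform_state(c(A = 0, H = 1, S = 1, Y = 0), g)
  r <- reaction_rhs(st, p)
  expect_equal(r$dA[2, 2], 0)
  expect_equal(r$dH[2, 2], -p[["nu"]] * 1)

  # hand-evaluated at the unit state: 0.002 - 0.16 + 0.02
  st1 <- uniform_state(c(A = 1, H = 1, S = 1, Y = 1), g)
  expect_equal(reaction_rhs(st1, p)$dA[1, 1], -0.138)

  # all-zero fields with no substrate production: an exact reaction root
  p0 <- rd_preset("spine", c0 = 0)
  st0 <- uniform_state(c(A = 0, H = 0, S = 0, Y = 0), g)
  r0 <- reaction_rhs(st0, p0)
  for (f in r0) expect_true(all(f == 0))

  # non-finite input is rejected with the field named
  bad <- st1
  bad$A[1, 1] <- NaN
  expect_error(reaction_rhs(bad, p), "field A")
})

test_that("laplacian matches the dense Neumann operator and conserves mass", {
  g <- rd_grid(4, 4, dx = 0.3)

  expect_true(all(rd_laplacian(matrix(3.7, 4, 4), g) == 0))

  set.seed(11)
  for (rep in 1:5) {
    f <- matrix(rnorm(16), 4, 4)
    L <- dense_neumann_laplacian(4, 4, 0.3)
    expect_equal(as.vector(rd_laplacian(f, g)), as.vector(L %*% as.vector(f)),
                 tolerance = 1e-13)
    expect_lt(abs(sum(rd_laplacian(f, g))), 1e-11)
  }

  expect_error(rd_laplacian(matrix(0, 3, 4), g), "shape")
})

test_that("one Euler step equals the hand-assembled update", {
  g <- rd_grid(3, 3, dx = 0.3)
  p <- rd_preset("spine", epsilon = 0.05)
  set.seed(7)
  st <- rd_state(matrix(runif(9, 0, 2), 3, 3), matrix(runif(9, 0.01, 1), 3, 3),
                 matrix(runif(9, 0, 2), 3, 3), matrix(runif(9, 0, 1), 3, 3))
  stepped <- rd_step(st, p, g, dt = 0.02)
  oracle <- euler_step_oracle(st, p, g, dt = 0.02)
  for (f in c("A", "H", "S", "Y")) {
    expect_equal(stepped[[f]], oracle[[f]], tolerance = 1e-13)
  }
  expect_equal(stepped$t, st$t + 0.02)

  # dt = 0 leaves the state untouched
  expect_identical(rd_step(st, p, g, dt = 0), st)
})

test_that("negative undershoot is clamped to zero and counted", {
  g <- rd_grid(3, 3, dx = 0.3)
  # pure strong degradation of H drives it negative in one big (stable) step
  p <- rd_params(c = 0, mu = 0, nu = 30, rho_A = 0, rho_H = 0, c0 = 0,
                 gamma = 0, epsilon = 0, D_A = 0.001, D_H = 0.002,
                 D_S = 0.001, d = 0, e = 0, f = 0)
  st <- uniform_state(c(A = 0, H = 1, S = 0, Y = 0), g)
  out <- rd_step(st, p, g, dt = 0.05)   # 1 - 0.05*30 = -0.5 -> clamped
  expect_true(all(out$H == 0))
  expect_equal(attr(out, "clamp_count"), 9)
})

test_that("simulate composes, is deterministic, and records as scheduled", {
  g <- rd_grid(8, 8, dx = 0.3)
  p <- rd_preset("spine", epsilon = 0.05)
  set.seed(3)
  st <- rd_state(matrix(runif(64, 0, 2), 8, 8), matrix(runif(64, 0.01, 1), 8, 8),
                 matrix(runif(64, 0.5, 1.5), 8, 8), matrix(runif(64, 0, 1), 8, 8))

  # n_steps = 0: only the initial state
  tr0 <- rd_simulate(st, p, g, rd_schedule(n_steps = 0))
  expect_length(tr0$states, 1)
  expect_identical(tr0$states[[1]]$A, st$A)

  # composition: 30 + 20 steps == 50 steps, bitwise
  tr_a <- rd_simulate(st, p, g, rd_schedule(n_steps = 30))
  tr_b <- rd_simulate(final_state(tr_a), p, g, rd_schedule(n_steps = 20))
  tr_c <- rd_simulate(st, p, g, rd_schedule(n_steps = 50))
  for (f in c("A", "H", "S", "Y")) {
    expect_identical(final_state(tr_b)[[f]], final_state(tr_c)[[f]])
  }

  # determinism, including seeded noise
  s_n <- rd_schedule(n_steps = 40, noise_amp = 0.01, seed = 99)
  r1 <- rd_simulate(st, p, g, s_n)
  r2 <- rd_simulate(st, p, g, s_n)
  expect_identical(final_state(r1)$A, final_state(r2)$A)

  # snapshots every 10 steps: 1 initial + 5 recorded
  tr_r <- rd_simulate(st, p, g, rd_schedule(n_steps = 50, record_every = 10))
  expect_length(tr_r$states, 6)
  expect_true(all(diff(tr_r$times) > 0))
})

test_that("pure diffusion conserves each field total", {
  g <- rd_grid(10, 10, dx = 0.3)
  p <- rd_params(c = 0, mu = 0, nu = 0, rho_A = 0, rho_H = 0, c0 = 0,
                 gamma = 0, epsilon = 0, D_A = 0.02, D_H = 0.26, D_S = 0.06,
                 d = 0, e = 0, f = 0)
  set.seed(5)
  st <- rd_state(matrix(runif(100), 10, 10), matrix(runif(100), 10, 10),
                 matrix(runif(100), 10, 10), matrix(0, 10, 10))
  tr <- rd_simulate(st, p, g, rd_schedule(n_steps = 200))
  fin <- final_state(tr)
  for (f in c("A", "H", "S")) {
    expect_equal(sum(fin[[f]]), sum(st[[f]]), tolerance = 1e-12)
  }
  expect_equal(tr$clamp_count, 0)
})

test_that("a uniform reaction fixed point is stationary under simulation", {
  g <- rd_grid(12, 12, dx = 0.3)
  p <- rd_preset("spine")
  # (A, H, S, Y) = (0, 0, c0/gamma, 0) is an exact uniform root
  st <- uniform_state(c(A = 0, H = 0, S = 1, Y = 0), g)
  tr <- rd_simulate(st, p, g, rd_schedule(n_steps = 500))
  fin <- final_state(tr)
  for (f in c("A", "H", "S", "Y")) {
    expect_lt(max(abs(fin[[f]] - st[[f]])), 1e-12)
    expect_lt(stats::sd(fin[[f]]), 1e-10)
  }
})

test_that("initial protocol states carry the documented seed", {
  st <- make_initial_single_spine()
  expect_equal(sum(st$Y == 1), 50)            # 5 x 10 seed
  expect_equal(dim(st$A), c(100, 100))
  sc <- attr(st, "seed_cols"); sr <- attr(st, "seed_rows")
  expect_equal(length(sc), 5)
  expect_equal(length(sr), 10)
  expect_true(all(st$A[sr, sc] == 2))
  expect_true(all(st$H[sr, sc] == 0.02))
  expect_true(all(st$A[-sr, ] == 0.001))
  expect_true(all(st$Y[, -sc] == 0))
  expect_true(all(st$S == 1))
  # the thresholded mask is exactly the seed rectangle
  m <- cell_mask(st$Y)
  expect_equal(sum(m), 50)
  expect_true(all(m[sr, sc]))

  st2 <- make_initial_dendrite()
  expect_equal(dim(st2$A), c(200, 150))
  expect_equal(sum(st2$Y == 1), 50)
  expect_identical(st2, make_initial_dendrite())  # no hidden randomness

  expect_error(make_initial_single_spine(rd_grid(4, 4)), "fit")
})

test_that("the schedule constructor rejects unstable time steps", {
  p <- rd_preset("spine")
  g <- rd_grid(10, 10, dx = 0.3)
  # bound = 0.09 / (4 * 0.26) = 0.0865
  expect_error(rd_schedule(dt = 0.1, n_steps = 10, params = p, grid = g),
               "stability")
  expect_silent(rd_schedule(dt = 0.05, n_steps = 10, params = p, grid = g))
  st <- uniform_state(c(A = 0, H = 0, S = 1, Y = 0), g)
  expect_error(rd_simulate(st, p, g, rd_schedule(dt = 0.1, n_steps = 10)),
               "stability")
})

test_that("halving the time step leaves the formed spine unchanged", {
  tr1 <- simulate_spine(epsilon = 0.01, t_end = 800, dt = 0.05)
  tr2 <- simulate_spine(epsilon = 0.01, t_end = 800, dt = 0.025)
  dY <- abs(final_state(tr1)$Y - final_state(tr2)$Y)
  expect_lt(max(dY), 0.01)
  expect_equal(tr1$clamp_count, 0)
})

test_that("state checkpoints round-trip bit-exactly and export to PNG", {
  g <- rd_grid(7, 9)
  set.seed(2)
  st <- rd_state(matrix(runif(63), 7, 9), matrix(runif(63), 7, 9),
                 matrix(runif(63), 7, 9), matrix(runif(63), 7, 9), t = 3.5)
  path <- tempfile(fileext = ".rds")
  write_state(st, path)
  back <- read_state(path)
  expect_identical(back$A, st$A)
  expect_identical(back$t, st$t)

  png_path <- tempfile(fileext = ".png")
  write_state_png(st, png_path, field = "Y")
  img <- png::readPNG(png_path)
  expect_equal(dim(img)[1:2], c(7, 9))

  expect_error(rd_state(matrix(1, 2, 2), matrix(1, 2, 2),
                        matrix(1, 2, 2), matrix(-1, 2, 2)), "negative")
})

test_that("model parameters are validated", {
  expect_error(rd_params(mu = -1), "non-negative")
  expect_warning(rd_params(D_A = 0.3, D_H = 0.2), "lateral inhibition")
  p <- rd_preset("dendrite_trunk")
  expect_equal(p[["rho_A"]], 0.03)
  expect_equal(p[["epsilon"]], 0.017)
  expect_equal(rd_preset("dendrite_spines")[["c0"]], 0.05)
})
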