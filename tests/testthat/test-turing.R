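test_that("the frozen steady state matches closed form and brute force", {
  p <- rd_preset("spine")

  # Y = 0 closed form: A* = nu/mu, H* = c S A*^2 / nu
  ss <- ah_steady_state(1, 0, p)
  expect_equal(ss$A, 0.04 / 0.16, tolerance = 1e-10)
  expect_equal(ss$H, 0.002 * 1 * 0.25^2 / 0.04, tolerance = 1e-10)

  # residuals of both reaction equations vanish at returned roots
  p2 <- rd_preset("dendrite_spines")
  for (sy in list(c(1, 1), c(0.5, 0.4), c(2, 0.9), c(0.3, 0.1))) {
    ss <- ah_steady_state(sy[1], sy[2], p2)
    expect_true(ss$exists)
    res <- ah_reaction(ss$A, ss$H, sy[1], sy[2], p2)
    expect_lt(abs(res[["f"]]), 1e-10)
    expect_lt(abs(res[["g"]]), 1e-10)
  }

  # agreement with the dense-scan oracle
  for (sy in list(c(1, 1), c(0.6, 0.45), c(1.5, 0.2))) {
    ss <- ah_steady_state(sy[1], sy[2], p2)
    roots <- bruteforce_ah_steady(sy[1], sy[2], p2)
    expect_true(min(abs(roots - ss$A)) < 1e-8 * max(1, ss$A))
  }
})

test_that("the closed-form Jacobian matches finite differences", {
  p <- rd_preset("dendrite_spines")
  set.seed(21)
  for (i in 1:20) {
    A <- runif(1, 0.05, 3); H <- runif(1, 0.01, 2)
    S <- runif(1, 0.1, 2); Y <- runif(1, 0, 1.5)
    J <- ah_jacobian(A, H, S, p)
    expect_equal(J$g_H, -p[["nu"]])       # linear degradation, exactly
    expect_lt(J$f_H, 0)
    expect_gt(J$g_A, 0)
    fd <- fd_ah_jacobian(A, H, S, Y, p)
    for (nm in c("f_A", "f_H", "g_A", "g_H")) {
      expect_equal(J[[nm]], unname(fd[[nm]]),
                   tolerance = 1e-6 * max(1, abs(J[[nm]])))
    }
  }
  expect_error(ah_jacobian(1, 0, 1, p), "positive")
})

test_that("the closed-form dispersion relation matches an eigensolver", {
  jacs <- seeded_random_jacobians(100, seed = 17)
  k <- exp(seq(log(0.05), log(8), length.out = 20))
  for (J in jacs) {
    dc <- dispersion_curve(J, D_A = 0.02, D_H = 0.26, k = k)
    for (i in seq_along(k)) {
      m <- matrix(c(J$f_A - k[i]^2 * 0.02, J$g_A,
                    J$f_H, J$g_H - k[i]^2 * 0.26), 2, 2)
      expect_equal(dc$re_lambda[i], eig_lambda_max(m), tolerance = 1e-10)
    }
  }

  # k = 0 reduces to the undiffused Jacobian; zero diffusion is flat in k
  J <- jacs[[1]]
  m0 <- matrix(c(J$f_A, J$g_A, J$f_H, J$g_H), 2, 2)
  expect_equal(dispersion_curve(J, 0.02, 0.26, 0)$re_lambda,
               eig_lambda_max(m0), tolerance = 1e-12)
  flat <- dispersion_curve(J, 0, 0, k)$re_lambda
  expect_true(all(abs(flat - flat[1]) < 1e-12))
})

test_that("equal diffusivities never yield Turing instability", {
  p <- suppressWarnings(rd_preset("dendrite_spines", D_H = 0.02))  # = D_A
  set.seed(31)
  for (i in 1:25) {
    S <- runif(1, 0.1, 2); Y <- runif(1, 0, 1.5)
    expect_false(as.logical(is_turing_unstable(S, Y, p)))
  }
})

test_that("inequality and dispersion instability tests agree", {
  p <- rd_preset("dendrite_spines")
  set.seed(41)
  for (i in 1:50) {
    S <- runif(1, 0, 2); Y <- runif(1, 0, 2)
    expect_identical(as.logical(is_turing_unstable(S, Y, p, "inequality")),
                     as.logical(is_turing_unstable(S, Y, p, "dispersion")))
  }
})

test_that("the instability raster is pure and responds to exogenous terms", {
  p0 <- rd_preset("dendrite_spines", delta_A = 0)
  p2 <- rd_preset("dendrite_spines", delta_A = 0.02)
  win <- c(0.2, 1.0)
  ts_a <- turing_space(p0, win, win, resolution = 15)
  ts_b <- turing_space(p0, win, win, resolution = 15)
  ts_c <- turing_space(p2, win, win, resolution = 15)
  expect_identical(ts_a$unstable, ts_b$unstable)   # pure function
  expect_false(identical(ts_a$unstable, ts_c$unstable))

  # resolution 1 is a single point evaluation
  one <- turing_space(p0, c(0.5, 0.5), c(0.4, 0.4), resolution = 1)
  expect_equal(one$unstable[1, 1],
               as.logical(is_turing_unstable(0.5, 0.4, p0)))
})

test_that("the wavelength maximizes the dispersion curve", {
  p <- rd_preset("dendrite_spines")
  # a point inside the instability band
  S <- 0.45; Y <- 0.37
  expect_true(as.logical(is_turing_unstable(S, Y, p)))
  tw <- turing_wavelength(S, Y, p)
  expect_true(tw$unstable)
  expect_equal(tw$wavelength, 2 * pi / tw$k_m, tolerance = 1e-12)
  expect_gt(tw$lambda_m, 0)

  # dense-grid brute force agrees with the refined maximizer
  ss <- ah_steady_state(S, Y, p)
  J <- ah_jacobian(ss$A, ss$H, S, p)
  k_dense <- exp(seq(log(0.01), log(10), length.out = 1e6))
  re <- dispersion_curve(J, p[["D_A"]], p[["D_H"]], k_dense)$re_lambda
  expect_equal(tw$k_m, k_dense[which.max(re)], tolerance = 1e-3)

  # a diffusively stable point reports no wavelength, with a reason
  tw0 <- turing_wavelength(2, 2, p)
  expect_false(tw0$unstable)
  expect_true(is.na(tw0$wavelength))
})

test_that("instability flags and finite wavelengths coincide", {
  p <- rd_preset("dendrite_spines")
  set.seed(55)
  for (i in 1:15) {
    S <- runif(1, 0.2, 1); Y <- runif(1, 0.1, 0.8)
    flag <- as.logical(is_turing_unstable(S, Y, p))
    tw <- turing_wavelength(S, Y, p)
    expect_identical(flag, tw$unstable)
    expect_identical(flag, is.finite(tw$wavelength))
  }
})

test_that("the unstable region shrinks to nothing as D_H approaches D_A", {
  win_S <- c(0.2, 1.0); win_Y <- c(0.1, 0.7)
  frac <- sapply(c(0.26, 0.1, 0.05, 0.03, 0.021), function(dh) {
    p <- rd_preset("dendrite_spines", D_H = dh)
    mean(turing_space(p, win_S, win_Y, resolution = 12)$unstable)
  })
  expect_true(all(diff(frac) <= 0))
  expect_equal(frac[length(frac)], 0)
})

test_that("the S-Y readout of a trajectory is a faithful lookup", {
  g <- rd_grid(6, 6)
  p <- rd_preset("spine")
  st <- uniform_state(c(A = 0, H = 0, S = 1, Y = 0), g)  # reaction root
  tr <- rd_simulate(st, p, g, rd_schedule(n_steps = 50, record_every = 10))
  cur <- sy_trajectory(tr, c(3, 4))
  expect_equal(nrow(cur), length(tr$states))
  expect_true(all(cur$S == 1) && all(cur$Y == 0))   # frozen at the root
  expect_equal(cur$S, vapply(tr$states, function(s) s$S[3, 4], numeric(1)))
  expect_error(sy_trajectory(tr, c(7, 1)), "outside")

  # a frozen non-Turing curve has no intersection; the contract holds
  res <- analyze_point(tr, c(3, 4))
  expect_false(res$in_turing_space)
  expect_equal(res$reason, "no intersection")
  expect_true(is.na(res$wavelength))
})
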