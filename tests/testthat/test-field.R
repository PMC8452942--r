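test_that("explicit scheme enforces its stability bound", {
  p <- load_params() # D = 7.6, dx = 10, dt = 1: r = 0.076 <= 1/6
  f <- chemokine_field(c(100, 100, 100), 10, 1)
  expect_no_error(step_field(f, NULL, p, 1))
  p2 <- load_params(list(diffusion_coeff = 146))
  f2 <- chemokine_field(c(100, 100, 100), 10, 2) # r = 2.92 > 1/6
  expect_error(step_field(f2, NULL, p2, 1), "dt <=")
})

test_that("decay-only dynamics follow the exponential closed form", {
  p <- load_params(list(diffusion_coeff = 0))
  f <- chemokine_field(c(50, 50, 50), 10, 1)
  f$grid[3, 3, 3] <- 1000
  f2 <- step_field(f, NULL, p, n_steps = 120)
  expect_equal(f2$grid[3, 3, 3], 1000 * exp(-0.007 * 120),
               tolerance = 1e-12)
  expect_equal(sum(f2$grid), 1000 * exp(-0.007 * 120), tolerance = 1e-12)
})

test_that("pure diffusion conserves mass and non-negativity", {
  p <- load_params(list(decay_rate = 0))
  f <- chemokine_field(c(80, 80, 80), 10, 1)
  set.seed(42)
  f$grid[] <- runif(length(f$grid), 0, 100)
  m0 <- sum(f$grid)
  f2 <- step_field(f, NULL, p, n_steps = 1000)
  expect_lt(abs(sum(f2$grid) - m0) / m0, 1e-9)
  expect_true(all(f2$grid >= 0))
})

test_that("a point source relaxes to the 3-D heat kernel", {
  p <- load_params(list(decay_rate = 0))
  f <- chemokine_field(c(210, 210, 210), 10, 1)
  M0 <- 1e6
  f$grid[11, 11, 11] <- M0
  f2 <- step_field(f, NULL, p, n_steps = 50)
  # analytic voxel masses: separable Gaussian integrated over voxel faces
  s1 <- sqrt(2 * p$diffusion_coeff * 50)
  ctr <- 10.5 * 10
  xs <- (seq_len(21) - 1) * 10
  m1 <- pnorm((xs + 10 - ctr) / s1) - pnorm((xs - ctr) / s1)
  exact <- M0 * outer(outer(m1, m1), m1)
  expect_lt(sum(abs(f2$grid - exact)) / sum(exact), 0.05)
})

test_that("secretion with decay approaches the S/lambda steady state", {
  p <- load_params(list(decay_rate = 0.01))
  net <- generate_network(downscale_params(load_params(), 0.02), seed = 1)
  f <- chemokine_field(c(80, 80, 90), 10, 1)
  n_steps <- ceiling(6 / p$decay_rate) # 6 decay time constants
  f2 <- step_field(f, net, p, n_steps = n_steps)
  S <- sum(mass_to_molecules(net$nodes$secretion_rate))
  # continuous-time steady state, up to the O(lambda*dt) splitting bias
  expect_equal(sum(f2$grid), S / p$decay_rate, tolerance = 0.01)
  # discrete fixed point of the secrete-then-decay update, sharper
  dec <- exp(-p$decay_rate * f$dt_mol)
  expect_equal(sum(f2$grid), S * f$dt_mol * dec / (1 - dec),
               tolerance = 0.005)
})

test_that("mass-rate and concentration unit bridges are exact", {
  expect_equal(mass_to_molecules(0), 0)
  # 0.18 fg/min of a 10.3 kDa protein is ~175 molecules per second
  expect_equal(mass_to_molecules(0.18),
               0.18e-15 / 10300 * 6.02214076e23 / 60)
  expect_equal(round(mass_to_molecules(0.18)), 175)
  expect_equal(mass_to_molecules(0.6), 2 * mass_to_molecules(0.3))
  # a (10 um)^3 voxel is 1 pL: 10 nM is ~6022 molecules
  f <- chemokine_field(c(30, 30, 30), 10, 1)
  expect_equal(concentration_at(f, c(15, 15, 15)), 0)
  f$grid[2, 2, 2] <- 10e-9 * 1e-12 * 6.02214076e23
  expect_equal(concentration_at(f, c(15, 15, 15)), 10, tolerance = 1e-12)
  f$grid[2, 2, 2] <- 2 * f$grid[2, 2, 2] # linear in amount
  expect_equal(concentration_at(f, c(15, 15, 15)), 20, tolerance = 1e-12)
  expect_error(concentration_at(f, c(100, 0, 0)), "outside")
})

test_that("field snapshots export as long-format CSV", {
  f <- chemokine_field(c(30, 30, 30), 10, 1)
  f$grid[1, 1, 1] <- 602.214076
  path <- file.path(tempdir(), "field.csv")
  write_field_csv(f, path)
  tab <- read.csv(path)
  expect_equal(nrow(tab), 27)
  expect_equal(tab$conc_nM[tab$i == 1 & tab$j == 1 & tab$k == 1], 1,
               tolerance = 1e-6)
})
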