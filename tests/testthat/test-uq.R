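test_that("A-test identities and tie handling are exact", {
  expect_equal(a_test(c(1, 2, 3), c(1, 2, 3))$statistic, 0.5)
  expect_equal(a_test(c(1, 2, 3), c(1, 2, 3))$effect_class, "none")
  expect_equal(a_test(4:6, 1:3)$statistic, 1)
  expect_equal(a_test(1:3, 4:6)$statistic, 0)
  expect_equal(a_test(4:6, 1:3)$effect_class, "large")
  # tie rule: 4 pairs = 1 win, 1 loss, 2 ties -> 0.5
  expect_equal(a_test(c(1, 2), c(1, 2))$statistic, 0.5)
  expect_error(a_test(numeric(0), 1:3), "nonempty")
})

test_that("A-test is antisymmetric and classes follow the thresholds", {
  set.seed(1)
  for (i in 1:20) {
    a <- rnorm(sample(3:30, 1))
    b <- rnorm(sample(3:30, 1), mean = runif(1, -2, 2))
    expect_equal(a_test(a, b)$statistic + a_test(b, a)$statistic, 1)
  }
  # crafted statistics on either side of each threshold:
  # 56/100 wins -> 0.56 -> "small"; just below -> "none"
  a <- c(rep(1, 44), rep(3, 56))
  b <- rep(2, 100)
  expect_equal(a_test(a, b)$statistic, 0.56)
  expect_equal(a_test(a, b)$effect_class, "small")
  a2 <- c(rep(1, 45), rep(3, 55))
  expect_equal(a_test(a2, b)$effect_class, "none")
  a3 <- c(rep(1, 34), rep(3, 66))
  expect_equal(a_test(a3, b)$effect_class, "medium")
  a4 <- c(rep(1, 29), rep(3, 71))
  expect_equal(a_test(a4, b)$effect_class, "large")
})

test_that("aleatory analysis finds stable outputs stable and noise noisy", {
  # degenerate simulator returning a constant: all A = 0.5 at every size
  pool <- matrix(5, 400, 2, dimnames = list(NULL, c("m1", "m2")))
  out <- aleatory_analysis(pool, c(5, 20), n_subsets = 20)
  expect_true(all(out$max_a == 0.5))
  expect_equal(attr(out, "recommended"), 5)
  # n_subsets = 2: a single comparison per size
  out2 <- aleatory_analysis(matrix(rnorm(20), 20, 1), 10, n_subsets = 2)
  expect_equal(nrow(out2), 1)
  expect_error(aleatory_analysis(matrix(rnorm(20), 20, 1), 10,
                                 n_subsets = 20), "needs")
  # max |A - 0.5| decreases with sample size for a noisy generator
  set.seed(2)
  devs <- replicate(8, {
    pool <- matrix(rlnorm(3200), ncol = 1)
    o <- aleatory_analysis(pool, c(4, 160), n_subsets = 20)
    o$max_a_dev
  })
  expect_lt(median(devs[2, ]), median(devs[1, ]))
})

test_that("OAT robustness flags real perturbations and not the baseline", {
  p <- load_params()
  # toy simulator: deterministic response to k_des plus seeded noise
  toy <- function(params, seed) {
    set.seed(seed)
    c(speed = 10 * params$k_des + rnorm(1, 0, 0.05),
      scanning = 5 + rnorm(1, 0, 0.1))
  }
  out <- oat_robustness(p, "k_des", values = c(0.075, 0.01),
                        runs_per_value = 50, simulator = toy,
                        master_seed = 1)
  self <- out[out$value == 0.075 & out$metric == "speed", ]
  expect_gt(self$a_statistic, 0.4)
  expect_lt(self$a_statistic, 0.6)
  pert <- out[out$value == 0.01 & out$metric == "speed", ]
  expect_true(pert$significant)
  expect_false(out[out$value == 0.01 & out$metric == "scanning",
                   "significant"])
  expect_error(oat_robustness(p, "nope", 1, 2, toy), "unknown parameter")
})

test_that("Latin-hypercube marginals hit every stratum exactly once", {
  rg <- param_ranges(sampled_only = TRUE)
  X <- lhc_design(rg, 40, seed = 1)
  for (j in which(rg$high > rg$low)) {
    u <- (X[, j] - rg$low[j]) / (rg$high[j] - rg$low[j])
    expect_equal(sort(findInterval(u, seq(0, 1, length.out = 41),
                                   rightmost.closed = TRUE)), 1:40)
  }
  # constant parameter: all samples at its single value
  expect_true(all(X[, "signal_threshold"] == 10))
})

test_that("PRCC recovers monotone drivers and ignores noise", {
  rg <- data.frame(name = paste0("x", 1:4), low = 0, high = 1)
  set.seed(3)
  X <- lhc_design(rg, 500)
  # response equal to one parameter: PRCC 1 (identical rank residuals)
  out <- prcc(X, X[, 1])
  expect_equal(out$prcc[1], 1, tolerance = 1e-8)
  # independent parameters stay near zero
  expect_true(all(abs(out$prcc[2:4]) < 0.1))
  # monotone-transform invariance (rank-based)
  y <- X[, 2]^2 + 0.2 * X[, 3]
  expect_equal(prcc(X, exp(4 * y))$prcc, prcc(X, y)$prcc,
               tolerance = 1e-12)
  # constant response -> flagged zeros
  out0 <- prcc(X, rep(1, 500))
  expect_true(all(out0$prcc == 0))
  expect_true(all(out0$degenerate))
  expect_error(prcc(X[1:5, ], X[1:5, 1]), "more samples")
})

test_that("lhc_prcc wires design, model and report together", {
  rg <- data.frame(name = c("a", "b"), low = c(0, 0), high = c(1, 1))
  rep <- lhc_prcc(rg, 100, model = function(X) {
    cbind(up = X[, 1], flat = rep(2, nrow(X)))
  }, seed = 4)
  expect_s3_class(rep, "sensitivity_report")
  expect_equal(rep$prcc[rep$response == "up" & rep$parameter == "a"], 1,
               tolerance = 1e-8)
  expect_true(all(rep$degenerate[rep$response == "flat"]))
})

test_that("quartile surrogates and calibration scoring behave", {
  # the surrogate matches the printed median and the log-scale IQR width
  s <- surrogate_from_quartiles(8.0, 2.3, 10.3, 20000, seed = 1)
  q <- quantile(s, c(0.25, 0.5, 0.75))
  expect_equal(unname(q[2]), 8.0, tolerance = 0.05)
  expect_equal(unname(log(q[3] / q[1])), log(10.3 / 2.3), tolerance = 0.05)
  expect_error(surrogate_from_quartiles(1, 2, 3, 10), "q1 <= median")

  set.seed(5)
  x <- rlnorm(30, log(8), 0.5)
  cal <- calibration_score(list(velocity = x), list(velocity = x))
  expect_true(all(cal$pass))
  far <- calibration_score(list(velocity = x + 100),
                           list(velocity = c(8.0, 2.3, 10.3)))
  expect_false(any(far$pass))
  expect_error(calibration_score(list(a = x), NULL), "reference missing")
  expect_error(calibration_score(list(a = x), list(b = 1:3)), "shared")
  expect_true(passes_calibration(cal))
  expect_false(passes_calibration(cal, far))
})
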