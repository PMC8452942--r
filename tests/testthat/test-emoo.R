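test_that("training-set construction has the documented shape and splits", {
  p <- load_params()
  # toy run-level simulator: cheap deterministic function of the parameters
  toy <- function(params, seed) {
    set.seed(seed)
    v <- sampled_vector(params)
    c(velocity = params$displacement_constant + rnorm(1, 0, 0.01),
      meandering_index = 0.5 + 1e-6 * v[["r_total"]],
      motility_coefficient = 3 + params$alpha1,
      scanning_rate = 10 + v[["k_on"]] / 1e5 + rnorm(1, 0, 0.1))
  }
  d <- build_training_set(p, n_sets = 2, runs_per_set = 1,
                          master_seed = 1, simulator = toy)
  expect_equal(dim(d$inputs), c(2, 13))
  expect_equal(dim(d$outputs), c(2, 4))
  rg <- param_ranges(sampled_only = TRUE)
  for (j in 1:13) {
    expect_true(all(d$inputs[, j] >= rg$low[j] & d$inputs[, j] <= rg$high[j]))
  }
  d2 <- build_training_set(p, n_sets = 40, runs_per_set = 1,
                           master_seed = 2, simulator = toy)
  expect_equal(sum(d2$split == "train"), 30)
  expect_equal(sum(d2$split == "test"), 6)
  expect_equal(sum(d2$split == "validation"), 4)
})

test_that("the emulator learns a recoverable mapping", {
  rg <- param_ranges(sampled_only = TRUE)
  set.seed(9)
  n <- 120
  X <- lhc_design(rg, n)
  Xn <- follisim:::.norm_inputs(X, rg)
  A <- matrix(runif(13 * 4, -2, 2), 13, 4)
  Y <- Xn %*% A
  colnames(Y) <- c("velocity", "meandering_index", "motility_coefficient",
                   "scanning_rate")
  lab <- rep("validation", n)
  lab[1:90] <- "train"
  lab[91:108] <- "test"
  d <- structure(list(inputs = X, outputs = Y, split = lab, ranges = rg),
                 class = "emulator_dataset")
  e <- train_emulator(d, hidden_layer_candidates = 1:2, epochs = 800,
                      seed = 1)
  pred <- predict(e, X[109:120, ])
  r2 <- 1 - sum((pred - Y[109:120, ])^2) /
    sum(scale(Y[109:120, ], scale = FALSE)^2)
  expect_gt(r2, 0.95)
  expect_lt(e$test_mse, 0.01) # normalized scale
  # predictions are deterministic once trained
  expect_identical(predict(e, X[1:5, ]), predict(e, X[1:5, ]))
  # degenerate outputs are refused
  d0 <- d
  d0$outputs[, 1] <- 1
  expect_error(train_emulator(d0, 1, epochs = 10), "degenerate")
  d1 <- d
  d1$split <- rep("test", n)
  expect_error(train_emulator(d1, 1, epochs = 10), "training rows")
})

test_that("a no-signal dataset cannot beat the output variance", {
  rg <- param_ranges(sampled_only = TRUE)
  set.seed(10)
  n <- 80
  X <- lhc_design(rg, n)
  Y <- matrix(rnorm(n * 4), n, 4) # labels independent of inputs
  colnames(Y) <- c("velocity", "meandering_index", "motility_coefficient",
                   "scanning_rate")
  d <- structure(list(inputs = X, outputs = Y,
                      split = rep(c("train", "test"), c(64, 16)),
                      ranges = rg),
                 class = "emulator_dataset")
  e <- train_emulator(d, hidden_layer_candidates = 1, epochs = 400,
                      seed = 2)
  # normalized test MSE comparable to the variance of normalized outputs
  expect_gt(e$test_mse, 0.02)
})

test_that("NSGA-II approximates an analytic Pareto front", {
  sch <- function(X) cbind(X[, 1]^2, (X[, 1] - 2)^2)
  res <- nsga2(sch, lower = -3, upper = 5, pop_size = 60,
               generations = 100, seed = 1)
  front <- res$objectives[res$front, , drop = FALSE]
  # exhaustive non-domination check
  dom <- follisim:::.domination_matrix(front)
  expect_true(all(!dom[cbind(seq_len(nrow(front)), seq_len(nrow(front)))]))
  expect_equal(sum(dom), 0)
  # optimal set is x in [0, 2]
  expect_true(all(res$par[res$front, 1] > -0.1 &
                    res$par[res$front, 1] < 2.1))
  # hypervolume within 5% of the analytic front
  xs <- seq(0, 2, length.out = 2000)
  hv_true <- hypervolume_2d(cbind(xs^2, (xs - 2)^2), c(4.2, 4.2))
  hv_got <- hypervolume_2d(front, c(4.2, 4.2))
  expect_gt(hv_got / hv_true, 0.95)
})

test_that("dominance logic collapses degenerate objectives correctly", {
  # three constant objectives: the front reduces to the best fourth
  obj <- cbind(1, 1, 1, -c(1, 5, 3, 5))
  nd <- follisim:::.pareto_nondominated(obj)
  expect_equal(which(nd), c(2, 4))
  # constant dimensions stay fixed under the operators
  f <- function(X) cbind((X[, 1] - 1)^2, (X[, 1] + 1)^2)
  res <- nsga2(f, lower = c(-2, 5), upper = c(2, 5), pop_size = 20,
               generations = 10, seed = 2)
  expect_true(all(res$par[, 2] == 5))
})

test_that("the settings sweep reports one row per combination", {
  rg <- param_ranges(sampled_only = TRUE)
  set.seed(12)
  X <- lhc_design(rg, 60)
  Xn <- follisim:::.norm_inputs(X, rg)
  Y <- Xn %*% matrix(runif(13 * 4), 13, 4) + 1
  colnames(Y) <- c("velocity", "meandering_index", "motility_coefficient",
                   "scanning_rate")
  d <- structure(list(inputs = X, outputs = Y,
                      split = rep(c("train", "test"), c(48, 12)),
                      ranges = rg),
                 class = "emulator_dataset")
  e <- train_emulator(d, hidden_layer_candidates = 1, epochs = 200,
                      seed = 3)
  sw <- moo_settings_sweep(e, crossover_rates = c(0.5, 0.9),
                           mutation_rates = 0.1, generations = 10,
                           pop_size = 16, seed = 1)
  expect_equal(nrow(sw), 2)
  expect_true(all(sw$front_size >= 1))
  expect_true(all(is.finite(sw$mean_param_variance)))
})

test_that("front parameter distributions normalize and detect skew", {
  front <- structure(list(
    parameters = as.data.frame(matrix(
      rep(param_ranges(sampled_only = TRUE)$baseline, each = 4), 4, 13,
      dimnames = list(NULL, param_ranges(sampled_only = TRUE)$name)
    ))
  ), class = "pareto_front")
  fd <- front_parameter_distributions(front)
  agg <- tapply(fd$histograms$mass, fd$histograms$parameter, sum)
  expect_true(all(abs(agg - 1) < 1e-12)) # masses sum to 1
  expect_true(all(fd$skewness == 0))     # identical solutions: no skew
  # an asymmetric pile near the low end of the range skews positive
  front$parameters$k_off <- c(0.0011, 0.0012, 0.0013, 0.008)
  fd2 <- front_parameter_distributions(front)
  expect_gt(fd2$skewness[["k_off"]], 0.5)
})
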