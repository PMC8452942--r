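# Emulation and multi-objective optimization: Latin-hypercube training data
# from the simulator, a feed-forward neural-network emulator (13 parameter
# inputs -> 4 behaviour outputs), and NSGA-II over the emulator to find the
# receptor configurations trading off agreement with experimental migration
# statistics against antigen scanning.

.emulator_outputs <- c("velocity", "meandering_index",
                       "motility_coefficient", "scanning_rate")

#' Build an emulator training dataset from the simulator
#'
#' Draws a Latin-hypercube design over the 13 sampled parameter ranges,
#' executes each parameter set `runs_per_set` times to mitigate aleatory
#' uncertainty, and uses the median of the per-run medians of the four
#' behaviour outputs as the set's response row. Rows are partitioned into
#' training (75%), testing (15%) and validation (10%) splits.
#'
#' @param p base `simulation_params`; engine-scale fields (`n_bcells`,
#'   `duration`, `burn_in`) set the per-run problem size.
#' @param n_sets number of parameter sets (LHC design size).
#' @param runs_per_set replicate runs per set.
#' @param master_seed base seed; run j of set i uses
#'   `master_seed + (i - 1) * runs_per_set + j`.
#' @param simulator run-level function `(params, seed) -> named vector`
#'   (default [default_simulator()]).
#' @return an `emulator_dataset`: list with `inputs` (n x 13), `outputs`
#'   (n x 4), `split`, `ranges`.
#' @export
build_training_set <- function(p, n_sets = 1000, runs_per_set = 100,
                               master_seed = p$seed,
                               simulator = default_simulator()) {
  ranges <- param_ranges(sampled_only = TRUE)
  X <- lhc_design(ranges, n_sets, seed = master_seed)
  Y <- matrix(NA_real_, n_sets, length(.emulator_outputs),
              dimnames = list(NULL, .emulator_outputs))
  for (i in seq_len(n_sets)) {
    pp <- vector_to_params(stats::setNames(X[i, ], colnames(X)), base = p)
    runs <- vapply(seq_len(runs_per_set), function(j) {
      simulator(pp, master_seed + (i - 1) * runs_per_set + j)
    }, numeric(length(.emulator_outputs)))
    Y[i, ] <- apply(matrix(runs, nrow = length(.emulator_outputs)), 1,
                    stats::median)
  }
  set.seed(master_seed)
  n_train <- round(0.75 * n_sets)
  n_test <- round(0.15 * n_sets)
  lab <- rep("validation", n_sets)
  ord <- sample.int(n_sets)
  lab[ord[seq_len(n_train)]] <- "train"
  lab[ord[n_train + seq_len(min(n_test, n_sets - n_train))]] <- "test"
  structure(list(inputs = X, outputs = Y, split = lab, ranges = ranges),
            class = "emulator_dataset")
}

.norm_inputs <- function(X, ranges) {
  span <- ranges$high - ranges$low
  out <- sapply(seq_len(ncol(X)), function(j) {
    if (span[j] == 0) rep(0.5, nrow(X))
    else (X[, j] - ranges$low[j]) / span[j]
  })
  matrix(out, nrow(X), ncol(X))
}

#' Train the simulation emulator
#'
#' Min-max normalizes inputs (over the sampling ranges) and outputs (over
#' the training rows), then selects the network depth by ten-fold cross
#' validation over candidate structures with `hidden_layer_candidates`
#' hidden layers of `hidden_units` logistic units each, scoring each
#' structure by the mean across folds of the root mean squared error
#' between predicted and simulated responses. The selected structure is
#' refit on the full training split; held-out test and validation MSE are
#' reported.
#'
#' @param d an `emulator_dataset`.
#' @param hidden_layer_candidates depths to compare (default 1:4).
#' @param hidden_units units per hidden layer.
#' @param epochs training epochs per fit.
#' @param seed RNG seed (fold assignment and weight initialisation).
#' @return a `follisim_emulator` with elements `fit`, `cv_table`,
#'   `structure`, `test_mse`, `validation_mse`, plus the normalization
#'   constants; predictions via [predict.follisim_emulator()] are
#'   deterministic once trained.
#' @export
train_emulator <- function(d, hidden_layer_candidates = 1:4,
                           hidden_units = 8, epochs = 1500, seed = 1) {
  tr <- d$split == "train"
  if (sum(tr) < 10) stop("need at least 10 training rows")
  if (any(apply(d$outputs[tr, , drop = FALSE], 2, function(x) {
    diff(range(x)) == 0 || !all(is.finite(x))
  }))) {
    stop("degenerate (constant or non-finite) outputs; cannot emulate")
  }
  Xn <- .norm_inputs(d$inputs, d$ranges)
  out_min <- apply(d$outputs[tr, , drop = FALSE], 2, min)
  out_max <- apply(d$outputs[tr, , drop = FALSE], 2, max)
  Yn <- sweep(sweep(d$outputs, 2, out_min), 2, out_max - out_min, "/")

  set.seed(seed)
  Xtr <- Xn[tr, , drop = FALSE]; Ytr <- Yn[tr, , drop = FALSE]
  n <- nrow(Xtr)
  folds <- sample(rep(seq_len(10), length.out = n))
  cv <- data.frame(hidden_layers = hidden_layer_candidates,
                   mean_rmse = NA_real_)
  for (hi in seq_along(hidden_layer_candidates)) {
    depth <- hidden_layer_candidates[hi]
    rmse <- vapply(seq_len(10), function(f) {
      hold <- folds == f
      if (!any(hold) || sum(!hold) < 2) return(NA_real_)
      fit <- mlp_fit(Xtr[!hold, , drop = FALSE], Ytr[!hold, , drop = FALSE],
                     hidden = rep(hidden_units, depth), epochs = epochs,
                     seed = seed + 100 * depth + f)
      sqrt(mean((.mlp_predict(fit, Xtr[hold, , drop = FALSE]) -
                   Ytr[hold, , drop = FALSE])^2))
    }, numeric(1))
    cv$mean_rmse[hi] <- mean(rmse, na.rm = TRUE)
  }
  best <- hidden_layer_candidates[which.min(cv$mean_rmse)]
  fit <- mlp_fit(Xtr, Ytr, hidden = rep(hidden_units, best),
                 epochs = epochs, seed = seed)
  mse_on <- function(lbl) {
    idx <- d$split == lbl
    if (!any(idx)) return(NA_real_)
    mean((.mlp_predict(fit, Xn[idx, , drop = FALSE]) -
            Yn[idx, , drop = FALSE])^2)
  }
  structure(list(
    fit = fit, cv_table = cv, structure = rep(hidden_units, best),
    ranges = d$ranges, out_min = out_min, out_max = out_max,
    outputs = colnames(d$outputs),
    train_mse = mse_on("train"), test_mse = mse_on("test"),
    validation_mse = mse_on("validation")
  ), class = "follisim_emulator")
}

#' Predict simulator responses from the emulator
#'
#' @param object a `follisim_emulator`.
#' @param newdata matrix of parameter vectors (n x 13,
#'   [sampled_vector()] order) on the raw parameter scale.
#' @param ... unused.
#' @return n x 4 matrix of predicted behaviour outputs (raw scale).
#' @export
predict.follisim_emulator <- function(object, newdata, ...) {
  newdata <- matrix(as.numeric(newdata), ncol = nrow(object$ranges))
  Yn <- .mlp_predict(object$fit, .norm_inputs(newdata, object$ranges))
  out <- sweep(sweep(Yn, 2, object$out_max - object$out_min, "*"), 2,
               object$out_min, "+")
  colnames(out) <- object$outputs
  out
}

#' @export
print.follisim_emulator <- function(x, ...) {
  cat(sprintf(
    "Neural-network emulator: 13 -> %s -> %d, CV-selected depth %d\n",
    paste(x$structure, collapse = "-"), length(x$outputs),
    length(x$structure)
  ))
  cat(sprintf("  normalized MSE: train %.4g / test %.4g / validation %.4g\n",
              x$train_mse, x$test_mse, x$validation_mse))
  invisible(x)
}

# ---- NSGA-II --------------------------------------------------------------

.pareto_nondominated <- function(obj) {
  dom <- .domination_matrix(obj)
  colSums(dom) == 0
}

# dom[i, j] = TRUE iff solution i dominates solution j (all objectives <=,
# at least one <)
.domination_matrix <- function(obj) {
  le <- Reduce(`&`, lapply(seq_len(ncol(obj)), function(k) {
    outer(obj[, k], obj[, k], `<=`)
  }))
  lt <- Reduce(`|`, lapply(seq_len(ncol(obj)), function(k) {
    outer(obj[, k], obj[, k], `<`)
  }))
  le & lt
}

.nd_sort <- function(obj) {
  dom <- .domination_matrix(obj)
  n <- nrow(obj)
  count <- colSums(dom)
  rank <- integer(n)
  r <- 0L
  while (any(rank == 0L)) {
    r <- r + 1L
    cur <- which(rank == 0L & count == 0L)
    if (!length(cur)) break
    rank[cur] <- r
    for (i in cur) count <- count - dom[i, ]
    count[rank > 0L] <- Inf
  }
  rank
}

.crowding <- function(obj) {
  n <- nrow(obj)
  cd <- numeric(n)
  for (k in seq_len(ncol(obj))) {
    o <- order(obj[, k])
    rng <- obj[o[n], k] - obj[o[1], k]
    cd[o[c(1, n)]] <- Inf
    if (n > 2 && rng > 0) {
      cd[o[2:(n - 1)]] <- cd[o[2:(n - 1)]] +
        (obj[o[3:n], k] - obj[o[1:(n - 2)], k]) / rng
    }
  }
  cd
}

#' NSGA-II multi-objective genetic algorithm
#'
#' Elitist non-dominated sorting GA: binary tournament selection on
#' (rank, crowding distance), simulated binary crossover, polynomial
#' mutation, and (mu + lambda) environmental selection. All objectives are
#' minimized. Box constraints only; dimensions with `lower == upper` are
#' held fixed.
#'
#' @param obj_fn function: population matrix (rows = solutions) ->
#'   objective matrix.
#' @param lower,upper box constraints.
#' @param pop_size population size (default 100).
#' @param generations number of generations (default 300).
#' @param pc crossover probability (default 0.9).
#' @param pm per-gene mutation probability (default `1 / n_var`).
#' @param eta_c,eta_m SBX and polynomial-mutation distribution indices.
#' @param seed RNG seed.
#' @return list with `par` (final population), `objectives`, `rank`, and
#'   `front` (indices of the final non-dominated set).
#' @export
nsga2 <- function(obj_fn, lower, upper, pop_size = 100, generations = 300,
                  pc = 0.9, pm = NULL, eta_c = 15, eta_m = 20,
                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nv <- length(lower)
  if (is.null(pm)) pm <- 1 / nv
  span <- upper - lower
  varying <- span > 0

  P <- sweep(sweep(matrix(stats::runif(pop_size * nv), pop_size, nv), 2,
                   span, "*"), 2, lower, "+")
  O <- obj_fn(P)
  rank <- .nd_sort(O)
  cd <- unlist(lapply(split(seq_len(pop_size), rank), function(idx) {
    stats::setNames(.crowding(O[idx, , drop = FALSE]), idx)
  }))
  cd <- cd[order(as.integer(names(cd)))]

  tournament <- function() {
    i <- sample.int(pop_size, 1); j <- sample.int(pop_size, 1)
    if (rank[i] < rank[j]) i
    else if (rank[j] < rank[i]) j
    else if (cd[i] >= cd[j]) i else j
  }

  for (gen in seq_len(generations)) {
    C <- matrix(NA_real_, pop_size, nv)
    for (m in seq(1, pop_size, by = 2)) {
      p1 <- P[tournament(), ]; p2 <- P[tournament(), ]
      if (stats::runif(1) < pc) {
        for (v in which(varying)) {
          if (stats::runif(1) < 0.5 && abs(p1[v] - p2[v]) > 1e-14) {
            u <- stats::runif(1)
            beta <- if (u <= 0.5) (2 * u)^(1 / (eta_c + 1))
            else (1 / (2 * (1 - u)))^(1 / (eta_c + 1))
            c1 <- 0.5 * ((1 + beta) * p1[v] + (1 - beta) * p2[v])
            c2 <- 0.5 * ((1 - beta) * p1[v] + (1 + beta) * p2[v])
            p1[v] <- min(max(c1, lower[v]), upper[v])
            p2[v] <- min(max(c2, lower[v]), upper[v])
          }
        }
      }
      C[m, ] <- p1
      if (m + 1 <= pop_size) C[m + 1, ] <- p2
    }
    # polynomial mutation
    for (v in which(varying)) {
      mut <- stats::runif(pop_size) < pm
      if (any(mut)) {
        u <- stats::runif(sum(mut))
        delta <- ifelse(u < 0.5, (2 * u)^(1 / (eta_m + 1)) - 1,
                        1 - (2 * (1 - u))^(1 / (eta_m + 1)))
        C[mut, v] <- pmin(pmax(C[mut, v] + delta * span[v], lower[v]),
                          upper[v])
      }
    }
    OC <- obj_fn(C)
    allP <- rbind(P, C)
    allO <- rbind(O, OC)
    r <- .nd_sort(allO)
    keep <- integer(0)
    for (fr in sort(unique(r))) {
      idx <- which(r == fr)
      if (length(keep) + length(idx) <= pop_size) {
        keep <- c(keep, idx)
      } else {
        cdf <- .crowding(allO[idx, , drop = FALSE])
        keep <- c(keep, idx[order(cdf, decreasing = TRUE)][
          seq_len(pop_size - length(keep))])
        break
      }
    }
    P <- allP[keep, , drop = FALSE]
    O <- allO[keep, , drop = FALSE]
    rank <- .nd_sort(O)
    cd <- unlist(lapply(split(seq_len(pop_size), rank), function(idx) {
      stats::setNames(.crowding(O[idx, , drop = FALSE]), idx)
    }))
    cd <- cd[order(as.integer(names(cd)))]
  }
  front <- which(.pareto_nondominated(O))
  list(par = P, objectives = O, rank = rank, front = front)
}

#' Optimize receptor parameters over the emulator
#'
#' NSGA-II over the 13-parameter box with four objectives: minimize the
#' deviation of emulated cell speed, meandering index and motility
#' coefficient from the reference (calibration-anchor) values, and
#' maximize the emulated scanning rate.
#'
#' @param emulator a trained `follisim_emulator`.
#' @param references named vector of target behaviours; defaults to the
#'   printed wild-type medians (speed 8.0, meandering index 1.1, motility
#'   coefficient 15.6).
#' @param pop_size,generations,pc,pm,seed NSGA-II settings (defaults:
#'   population 100, 300 generations, crossover 0.9, mutation 1/13).
#' @return a `pareto_front`: list with `parameters` (front members, raw
#'   scale), `objectives`, `predictions` (emulated behaviours), and
#'   `references`.
#' @export
optimize_receptors <- function(emulator,
                               references = c(velocity = 8.0,
                                              meandering_index = 1.1,
                                              motility_coefficient = 15.6),
                               pop_size = 100, generations = 300, pc = 0.9,
                               pm = NULL, seed = 1) {
  rg <- emulator$ranges
  obj_fn <- function(X) {
    pr <- predict(emulator, X)
    cbind(
      speed_err = abs(pr[, "velocity"] - references[["velocity"]]),
      mi_err = abs(pr[, "meandering_index"] -
                     references[["meandering_index"]]),
      mc_err = abs(pr[, "motility_coefficient"] -
                     references[["motility_coefficient"]]),
      neg_scanning = -pr[, "scanning_rate"]
    )
  }
  res <- nsga2(obj_fn, rg$low, rg$high, pop_size = pop_size,
               generations = generations, pc = pc, pm = pm, seed = seed)
  fr <- res$front
  pars <- res$par[fr, , drop = FALSE]
  colnames(pars) <- rg$name
  structure(list(
    parameters = as.data.frame(pars),
    objectives = as.data.frame(res$objectives[fr, , drop = FALSE]),
    predictions = as.data.frame(predict(emulator, pars)),
    references = references
  ), class = "pareto_front")
}

#' Sweep NSGA-II settings
#'
#' Grid search over crossover rate, mutation rate and generation count,
#' re-running [optimize_receptors()] for each combination and summarising
#' front quality: the mean of each reference-deviation objective, the best
#' (most negative) scanning objective, and the mean variance of the
#' min-max-scaled front parameters (settings that perform well on the
#' objectives while keeping parameter variance high are preferred).
#'
#' @param emulator a trained `follisim_emulator`.
#' @param crossover_rates,mutation_rates,generations grids to sweep
#'   (defaults follow the 0.1-1.0 by 0.1 and 200-500 by 100 convention).
#' @param pop_size population size per run.
#' @param seed RNG seed (shared across combinations).
#' @param ... passed to [optimize_receptors()].
#' @return data.frame, one row per settings combination.
#' @export
moo_settings_sweep <- function(emulator,
                               crossover_rates = seq(0.1, 1, by = 0.1),
                               mutation_rates = seq(0.1, 1, by = 0.1),
                               generations = seq(200, 500, by = 100),
                               pop_size = 100, seed = 1, ...) {
  grid <- expand.grid(pc = crossover_rates, pm = mutation_rates,
                      generations = generations)
  rg <- emulator$ranges
  span <- rg$high - rg$low
  out <- NULL
  for (i in seq_len(nrow(grid))) {
    fr <- optimize_receptors(emulator, pop_size = pop_size,
                             generations = grid$generations[i],
                             pc = grid$pc[i], pm = grid$pm[i],
                             seed = seed, ...)
    scaled <- sweep(sweep(as.matrix(fr$parameters), 2, rg$low), 2,
                    pmax(span, .Machine$double.eps), "/")
    out <- rbind(out, data.frame(
      grid[i, ], front_size = nrow(fr$parameters),
      mean_speed_err = mean(fr$objectives$speed_err),
      mean_mi_err = mean(fr$objectives$mi_err),
      mean_mc_err = mean(fr$objectives$mc_err),
      best_scanning = -min(fr$objectives$neg_scanning),
      mean_param_variance = mean(apply(scaled[, span > 0, drop = FALSE],
                                       2, stats::var))
    ))
  }
  rownames(out) <- NULL
  out
}

#' @export
print.pareto_front <- function(x, ...) {
  cat(sprintf("Pareto front: %d non-dominated solutions, %d objectives\n",
              nrow(x$parameters), ncol(x$objectives)))
  invisible(x)
}

#' Parameter distributions along the Pareto front
#'
#' Min-max scales every front member's parameters to the sampling ranges
#' and reports a normalized histogram and the sample skewness per
#' parameter; positive skewness indicates mass piled at low scaled values
#' (tail towards high), negative the reverse.
#'
#' @param front a `pareto_front`.
#' @param bins number of histogram bins on \[0, 1\].
#' @return list with `histograms` (data.frame `parameter`, `bin_mid`,
#'   `mass`) and `skewness` (named vector).
#' @export
front_parameter_distributions <- function(front, bins = 10) {
  rg <- param_ranges(sampled_only = TRUE)
  hists <- NULL
  skew <- numeric(0)
  brk <- seq(0, 1, length.out = bins + 1)
  for (j in seq_len(nrow(rg))) {
    nm <- rg$name[j]
    x <- front$parameters[[nm]]
    span <- rg$high[j] - rg$low[j]
    xs <- if (span > 0) (x - rg$low[j]) / span else rep(0.5, length(x))
    cnt <- tabulate(pmin(pmax(findInterval(xs, brk, rightmost.closed = TRUE),
                              1), bins), nbins = bins)
    hists <- rbind(hists, data.frame(
      parameter = nm, bin_mid = (brk[-1] + brk[-(bins + 1)]) / 2,
      mass = cnt / length(xs)
    ))
    s <- stats::sd(xs)
    skew[nm] <- if (is.finite(s) && s > 0) {
      mean((xs - mean(xs))^3) / s^3
    } else 0
  }
  list(histograms = hists, skewness = skew)
}
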