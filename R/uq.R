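# Uncertainty quantification: Vargha-Delaney A-test, aleatory analysis,
# one-at-a-time robustness, Latin-hypercube + PRCC, and calibration scoring
# against experimental migration statistics.

.A_SMALL <- 0.56
.A_MEDIUM <- 0.66
.A_LARGE <- 0.71

#' Vargha-Delaney A-test
#'
#' Non-parametric effect-magnitude statistic: the probability that a
#' randomly selected sample from `a` is larger than one from `b`, ties
#' counted half. 0.5 means the two distributions are interchangeable; 1 and
#' 0 mean no overlap. Effect classes use the thresholds small 0.56, medium
#' 0.66 and large 0.71, applied symmetrically about 0.5.
#'
#' @param a,b numeric samples (nonempty).
#' @return an `a_test` object: list with `statistic` and `effect_class`
#'   (`"none"`, `"small"`, `"medium"`, `"large"`).
#' @examples
#' a_test(c(1, 2, 3), c(1, 2, 3))$statistic # 0.5
#' a_test(4:6, 1:3)$statistic               # 1
#' @export
a_test <- function(a, b) {
  if (!length(a) || !length(b)) stop("samples must be nonempty")
  n1 <- length(a); n2 <- length(b)
  r1 <- sum(rank(c(a, b))[seq_len(n1)])
  stat <- (r1 - n1 * (n1 + 1) / 2) / (n1 * n2) # wins + half-ties
  d <- abs(stat - 0.5) + 0.5
  cls <- if (d >= .A_LARGE) "large" else if (d >= .A_MEDIUM) "medium"
  else if (d >= .A_SMALL) "small" else "none"
  structure(list(statistic = stat, effect_class = cls), class = "a_test")
}

#' @export
print.a_test <- function(x, ...) {
  cat(sprintf("A-test statistic %.4f (effect: %s)\n", x$statistic,
              x$effect_class))
  invisible(x)
}

#' Aleatory uncertainty analysis
#'
#' Determines how many replicate runs are required for a representative
#' output distribution. For each candidate sample size, the pool of per-run
#' medians is split into `n_subsets` subsets of that size; subsets 2..n are
#' A-tested against subset 1 and the maximum deviation `|A - 0.5|` per
#' metric is reported. The recommended size is the smallest whose maxima
#' all stay below the medium-effect threshold (A within 0.5 +/- 0.16).
#'
#' @param pool matrix or data.frame of per-run medians (runs x metrics),
#'   e.g. the `medians` component of [run_batch()].
#' @param sample_sizes candidate runs-per-subset counts.
#' @param n_subsets number of subsets per sample size (>= 2; default 20).
#' @return data.frame `(sample_size, metric, max_a, max_a_dev)` with
#'   attribute `recommended` (NA when no candidate passes).
#' @export
aleatory_analysis <- function(pool, sample_sizes, n_subsets = 20) {
  pool <- as.matrix(pool)
  if (is.null(colnames(pool))) {
    colnames(pool) <- paste0("metric", seq_len(ncol(pool)))
  }
  if (n_subsets < 2) stop("n_subsets must be at least 2")
  out <- NULL
  for (k in sample_sizes) {
    if (k * n_subsets > nrow(pool)) {
      stop(sprintf("pool has %d runs; sample size %d x %d subsets needs %d",
                   nrow(pool), k, n_subsets, k * n_subsets))
    }
    ref <- pool[seq_len(k), , drop = FALSE]
    devs <- matrix(0, n_subsets - 1, ncol(pool))
    for (s in 2:n_subsets) {
      rows <- ((s - 1) * k + 1):(s * k)
      for (m in seq_len(ncol(pool))) {
        devs[s - 1, m] <- a_test(pool[rows, m], ref[, m])$statistic
      }
    }
    out <- rbind(out, data.frame(
      sample_size = k, metric = colnames(pool),
      max_a = apply(devs, 2, function(x) x[which.max(abs(x - 0.5))]),
      max_a_dev = apply(abs(devs - 0.5), 2, max), row.names = NULL
    ))
  }
  ok <- vapply(sample_sizes, function(k) {
    all(out$max_a_dev[out$sample_size == k] < (.A_MEDIUM - 0.5))
  }, logical(1))
  attr(out, "recommended") <- if (any(ok)) min(sample_sizes[ok]) else NA
  out
}

#' One-at-a-time parameter robustness
#'
#' Perturbs a single parameter across `values` with all others held at
#' their calibrated baseline, and A-tests each perturbed response
#' distribution against the baseline distribution, metric by metric. A
#' value is flagged as a significant behavioural alteration when its
#' statistic deviates beyond the medium-effect threshold 0.66 (or,
#' symmetrically, 0.34).
#'
#' @param p baseline `simulation_params`.
#' @param param_name name of the parameter to perturb.
#' @param values perturbed values.
#' @param runs_per_value replicate runs per value.
#' @param simulator function `(params, seed) -> named numeric vector` of
#'   run-level outputs; defaults to a scaled [run_simulation()] returning
#'   the per-run median of speed, meandering index, motility coefficient
#'   and scanning rate.
#' @param master_seed base seed; replicate i of every value uses
#'   `master_seed + i` so runs are paired across values.
#' @return data.frame `(parameter, value, metric, a_statistic,
#'   effect_class, significant)`.
#' @export
oat_robustness <- function(p, param_name, values, runs_per_value = 20,
                           simulator = default_simulator(),
                           master_seed = p$seed) {
  if (!param_name %in% names(p)) stop("unknown parameter: ", param_name)
  run_set <- function(pp) {
    do.call(rbind, lapply(seq_len(runs_per_value),
                          function(i) simulator(pp, master_seed + i)))
  }
  base <- run_set(p)
  out <- NULL
  for (v in values) {
    pp <- p
    pp[[param_name]] <- v
    pp <- validate_params(pp)
    pert <- run_set(pp)
    for (m in colnames(base)) {
      at <- a_test(pert[, m], base[, m])
      out <- rbind(out, data.frame(
        parameter = param_name, value = v, metric = m,
        a_statistic = at$statistic, effect_class = at$effect_class,
        significant = abs(at$statistic - 0.5) > (.A_MEDIUM - 0.5)
      ))
    }
  }
  rownames(out) <- NULL
  out
}

#' Default run-level simulator for the sensitivity routines
#'
#' Returns a closure `(params, seed) -> named vector` of per-run medians of
#' the four analysis outputs (velocity, meandering index, motility
#' coefficient, scanning rate) from one [run_simulation()] call.
#'
#' @export
default_simulator <- function() {
  function(params, seed) {
    r <- run_simulation(params, seed = seed)
    m <- r$metrics
    c(velocity = stats::median(m$velocity),
      meandering_index = stats::median(m$meandering_index),
      motility_coefficient = stats::median(m$motility_coefficient),
      scanning_rate = stats::median(m$scanning_rate))
  }
}

#' Latin-hypercube design
#'
#' Stratifies each varied parameter's range into `n` bins with one sample
#' per bin (via `lhs::randomLHS`); constant parameters (`low == high`) are
#' held at their single value.
#'
#' @param ranges data.frame with `name`, `low`, `high` (see
#'   [param_ranges()]).
#' @param n number of samples.
#' @param seed RNG seed.
#' @return an `n x nrow(ranges)` matrix with named columns.
#' @export
lhc_design <- function(ranges, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(ranges)
  u <- lhs::randomLHS(n, k)
  x <- sapply(seq_len(k), function(j) {
    ranges$low[j] + u[, j] * (ranges$high[j] - ranges$low[j])
  })
  x <- matrix(x, n, k)
  colnames(x) <- ranges$name
  x
}

#' Partial rank correlation coefficients
#'
#' Rank-transforms the design and the response; for each parameter, fits a
#' linear regression of its ranks on the other parameters' ranks and of the
#' response ranks on the other parameters' ranks, and reports the Pearson
#' correlation of the two residual vectors with a t-test against zero.
#' Constant parameters or a constant response yield PRCC 0 with
#' `degenerate = TRUE`.
#'
#' @param X design matrix (samples x parameters).
#' @param y response vector.
#' @return data.frame `(parameter, prcc, p_value, p_adj, degenerate)`
#'   (Benjamini-Hochberg adjusted p-values alongside the raw ones).
#' @export
prcc <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- ncol(X)
  if (n <= k + 2) stop("need more samples than parameters + 2")
  const <- apply(X, 2, function(c) diff(range(c)) == 0)
  ry <- rank(y)
  y_const <- diff(range(y)) == 0
  rX <- apply(X, 2, rank)
  vals <- numeric(k); pv <- numeric(k)
  for (j in seq_len(k)) {
    if (const[j] || y_const) {
      vals[j] <- 0; pv[j] <- 1
      next
    }
    others <- rX[, !const & seq_len(k) != j, drop = FALSE]
    r1 <- if (ncol(others)) stats::resid(stats::lm(rX[, j] ~ others))
    else rX[, j] - mean(rX[, j])
    r2 <- if (ncol(others)) stats::resid(stats::lm(ry ~ others))
    else ry - mean(ry)
    rho <- stats::cor(r1, r2)
    if (!is.finite(rho)) {
      vals[j] <- 0; pv[j] <- 1; const[j] <- TRUE
      next
    }
    vals[j] <- rho
    df <- n - 2 - (k - 1)
    tt <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
    pv[j] <- 2 * stats::pt(-abs(tt), df)
  }
  data.frame(
    parameter = colnames(X), prcc = vals, p_value = pv,
    p_adj = stats::p.adjust(pv, "BH"),
    degenerate = const | y_const, row.names = NULL
  )
}

#' Latin-hypercube sampling with PRCC sensitivity analysis
#'
#' Draws an LHC design over the parameter ranges, evaluates the model, and
#' computes PRCC per parameter and response.
#'
#' @param ranges data.frame `(name, low, high)`; defaults to the 13 sampled
#'   parameters.
#' @param n_samples design size (must exceed the parameter count + 2).
#' @param model function taking the design matrix and returning a response
#'   vector or matrix (columns = responses).
#' @param seed RNG seed for the design.
#' @return a `sensitivity_report` data.frame with one PRCC row per
#'   parameter-response pair, plus the design and responses as attributes.
#' @export
lhc_prcc <- function(ranges = param_ranges(sampled_only = TRUE), n_samples,
                     model, seed = NULL) {
  X <- lhc_design(ranges, n_samples, seed)
  y <- model(X)
  y <- as.matrix(y)
  if (is.null(colnames(y))) {
    colnames(y) <- paste0("response", seq_len(ncol(y)))
  }
  out <- do.call(rbind, lapply(colnames(y), function(r) {
    cbind(response = r, prcc(X, y[, r]))
  }))
  attr(out, "design") <- X
  attr(out, "responses") <- y
  class(out) <- c("sensitivity_report", class(out))
  out
}

#' Reconstruct a surrogate sample from printed quartiles
#'
#' Experimental migration statistics are printed as
#' `median [lower quartile - upper quartile]`; this draws a
#' quartile-matched log-normal surrogate: `meanlog = log(median)`,
#' `sdlog = (log(q3) - log(q1)) / (2 * qnorm(0.75))`.
#'
#' @param median,q1,q3 printed statistics (positive).
#' @param n surrogate sample size.
#' @param seed RNG seed.
#' @export
surrogate_from_quartiles <- function(median, q1, q3, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(c(median, q1, q3) <= 0) || q1 > median || median > q3) {
    stop("need 0 < q1 <= median <= q3")
  }
  stats::rlnorm(n, meanlog = log(median),
                sdlog = (log(q3) - log(q1)) / (2 * stats::qnorm(0.75)))
}

#' Calibration scoring against reference statistics
#'
#' For each metric: a Shapiro-Wilk normality check on the simulated sample
#' (motivating the non-parametric comparison), then a Mann-Whitney U test
#' of simulation vs reference. A metric passes when the two are not
#' significantly different at `alpha`. References are either raw samples or
#' printed `c(median, q1, q3)` triples, reconstructed via
#' [surrogate_from_quartiles()]. Constant simulated samples are reported
#' with `shapiro_p = NA` (normality rejected by construction).
#'
#' A parameter set is only retained when it passes against both the
#' wild-type and the gene-deficient references; apply this function per
#' condition and combine with [passes_calibration()].
#'
#' @param sim named list of simulated samples (e.g. per-run medians).
#' @param reference named list; each element a raw numeric sample or a
#'   length-3 `c(median, q1, q3)` triple.
#' @param alpha significance level (default 0.05).
#' @param n_surrogate surrogate sample size for triple references.
#' @param seed RNG seed for surrogate reconstruction.
#' @return data.frame `(metric, shapiro_p, mw_p, pass)`.
#' @export
calibration_score <- function(sim, reference, alpha = 0.05,
                              n_surrogate = 50, seed = 1) {
  if (is.null(reference) || !length(reference)) stop("reference missing")
  metrics <- intersect(names(sim), names(reference))
  if (!length(metrics)) stop("no shared metrics between sim and reference")
  out <- NULL
  for (m in metrics) {
    x <- sim[[m]]
    ref <- reference[[m]]
    if (length(ref) == 3L) {
      ref <- surrogate_from_quartiles(ref[1], ref[2], ref[3], n_surrogate,
                                      seed = seed)
    }
    sw <- tryCatch(stats::shapiro.test(x)$p.value, error = function(e) NA)
    mw <- stats::wilcox.test(x, ref, exact = FALSE)$p.value
    out <- rbind(out, data.frame(metric = m, shapiro_p = sw, mw_p = mw,
                                 pass = mw > alpha))
  }
  rownames(out) <- NULL
  out
}

#' @rdname calibration_score
#' @param ... calibration score tables (one per condition, e.g. wild-type
#'   and knockout).
#' @export
passes_calibration <- function(...) {
  all(vapply(list(...), function(s) all(s$pass), logical(1)))
}

#' Printed wild-type migration reference statistics
#'
#' Two-photon-imaging medians and quartiles for wild-type B cells: velocity
#' 8.0 \[2.3 - 10.3\] um min^-1, meandering index 1.1 \[0.1 - 2.4\],
#' motility coefficient 15.6 \[0.1 - 96.7\] um^2 min^-1.
#'
#' @return named list of `c(median, q1, q3)` triples.
#' @export
wt_reference <- function() {
  list(
    velocity = c(8.0, 2.3, 10.3),
    meandering_index = c(1.1, 0.1, 2.4),
    motility_coefficient = c(15.6, 0.1, 96.7)
  )
}
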