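# Extended Fourier Amplitude Sensitivity Test (eFAST).
#
# Each parameter in turn is assigned the maximum search frequency
# w_max = floor((NS - 1) / (2 * M)) while the complementary parameters get
# low frequencies (1 .. max(1, floor(w_max / (2 * M))), cycled). Parameter
# values follow x = 0.5 + asin(sin(w * s + phi)) / pi over NS points of
# s in (-pi, pi], rescaled to each range; a random phase shift phi per
# resample curve decorrelates repeat visits of the same points. First-order
# indices Si take the spectrum at the M harmonics of w_max; total-order
# indices STi subtract the complementary spectrum below w_max / 2. A dummy
# parameter with no effect on the model provides the null baseline for
# two-sample t-tests on the indices.

.efast_spectrum <- function(y, s, freqs) {
  y <- y - mean(y)
  vapply(freqs, function(w) {
    A <- mean(y * cos(w * s))
    B <- mean(y * sin(w * s))
    2 * (A^2 + B^2)
  }, numeric(1))
}

#' eFAST global sensitivity analysis
#'
#' Variance-decomposition sensitivity analysis with sinusoidal parameter
#' sampling. Reports, per parameter (including an inert `dummy`), the
#' first-order index `Si` (fraction of output variance explained by the
#' parameter alone) and the total-order index `STi` (variance involving the
#' parameter through any interaction), averaged over `n_curves` resample
#' curves with standard errors, plus two-sample t-tests of each parameter's
#' indices against the dummy's.
#'
#' @param ranges data.frame `(name, low, high)` of the parameters to vary.
#' @param model function: design matrix (columns named as `ranges$name`,
#'   the dummy column excluded) -> numeric response vector.
#' @param samples_per_curve odd number of samples per curve (NS); the
#'   maximum frequency is `floor((NS - 1) / (2 * M))` and must be >= 2,
#'   i.e. `NS >= 4 * M + 1`.
#' @param n_curves resample curves (default 3).
#' @param M number of harmonics (default 4).
#' @param seed RNG seed for the phase shifts.
#' @return a `sensitivity_report` data.frame
#'   `(parameter, Si, Si_se, STi, STi_se, Si_p, STi_p)`.
#' @export
efast <- function(ranges, model, samples_per_curve = 65, n_curves = 3,
                  M = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  NS <- samples_per_curve
  if (NS %% 2 == 0) stop("samples_per_curve must be odd")
  wmax <- floor((NS - 1) / (2 * M))
  if (wmax < 2) {
    stop(sprintf(
      "frequency aliasing: need samples_per_curve >= %d for M = %d harmonics",
      4 * M + 1, M
    ))
  }
  k <- nrow(ranges)
  nm <- c(ranges$name, "dummy")
  lo <- c(ranges$low, 0)
  hi <- c(ranges$high, 1)
  kk <- k + 1L
  wcomp_max <- max(1, floor(wmax / (2 * M)))
  s <- pi * (2 * seq_len(NS) - NS - 1) / NS

  Si <- matrix(NA_real_, kk, n_curves, dimnames = list(nm, NULL))
  STi <- matrix(NA_real_, kk, n_curves, dimnames = list(nm, NULL))

  for (i in seq_len(kk)) {
    freqs <- integer(kk)
    freqs[i] <- wmax
    freqs[-i] <- rep(seq_len(wcomp_max), length.out = kk - 1)
    for (cv in seq_len(n_curves)) {
      phi <- stats::runif(kk, 0, 2 * pi)
      X <- sapply(seq_len(kk), function(j) {
        x01 <- 0.5 + asin(sin(freqs[j] * s + phi[j])) / pi
        lo[j] + x01 * (hi[j] - lo[j])
      })
      colnames(X) <- nm
      y <- model(X[, seq_len(k), drop = FALSE])
      V <- sum(.efast_spectrum(y, s, seq_len((NS - 1) / 2)))
      if (V <= 0) {
        Si[i, cv] <- 0; STi[i, cv] <- 0
        next
      }
      Di <- sum(.efast_spectrum(y, s, wmax * seq_len(M)))
      Dcomp <- sum(.efast_spectrum(y, s, seq_len(floor(wmax / 2))))
      Si[i, cv] <- Di / V
      STi[i, cv] <- 1 - Dcomp / V
    }
  }

  ttest_p <- function(m) {
    vapply(seq_len(kk), function(i) {
      if (i == kk) return(NA_real_)
      tryCatch(stats::t.test(m[i, ], m[kk, ])$p.value,
               error = function(e) NA_real_)
    }, numeric(1))
  }
  se <- function(m) apply(m, 1, stats::sd) / sqrt(n_curves)
  out <- data.frame(
    parameter = nm,
    Si = rowMeans(Si), Si_se = se(Si),
    STi = rowMeans(STi), STi_se = se(STi),
    Si_p = ttest_p(Si), STi_p = ttest_p(STi),
    row.names = NULL
  )
  out$Si_p_adj <- stats::p.adjust(out$Si_p, "BH")
  out$STi_p_adj <- stats::p.adjust(out$STi_p, "BH")
  class(out) <- c("sensitivity_report", class(out))
  out
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("Sensitivity report\n")
  print.data.frame(x, digits = 3)
  invisible(x)
}
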