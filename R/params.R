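# Parameter vector: biological parameters (with sampling ranges used by all
# sensitivity analyses) plus engine settings (lattice/timestep/run length).

.param_table <- function() {
  # name, baseline, low, high, is_constant. "~" counts (FDC, BRC) are
  # stochastic targets at the network level but constants of the parameter
  # vector. Ranges are the ones used for uncertainty/sensitivity analyses.
  tab <- rbind(
    data.frame(name = "cell_diameter",         baseline = 7,      low = 7,      high = 7,     is_constant = TRUE),
    data.frame(name = "n_bcells",              baseline = 6000,   low = 6000,   high = 6000,  is_constant = TRUE),
    data.frame(name = "n_mrc",                 baseline = 100,    low = 100,    high = 100,   is_constant = TRUE),
    data.frame(name = "n_fdc",                 baseline = 200,    low = 200,    high = 200,   is_constant = TRUE),
    data.frame(name = "n_brc",                 baseline = 450,    low = 450,    high = 450,   is_constant = TRUE),
    data.frame(name = "cognate_fraction",      baseline = 0.05,   low = 0.05,   high = 0.05,  is_constant = TRUE),
    data.frame(name = "displacement_constant", baseline = 7.4,    low = 1,      high = 10,    is_constant = FALSE),
    data.frame(name = "signal_threshold",      baseline = 10,     low = 10,     high = 10,    is_constant = TRUE),
    data.frame(name = "max_turn_angle",        baseline = 180,    low = 180,    high = 180,   is_constant = TRUE),
    data.frame(name = "r_total",               baseline = 48000,  low = 1e4,    high = 1e5,   is_constant = FALSE),
    data.frame(name = "k_on",                  baseline = 4.8e5,  low = 1e5,    high = 1e6,   is_constant = FALSE),
    data.frame(name = "k_i",                   baseline = 0.0033, low = 0.001,  high = 0.01,  is_constant = FALSE),
    data.frame(name = "k_des",                 baseline = 0.075,  low = 0.01,   high = 0.1,   is_constant = FALSE),
    data.frame(name = "k_r",                   baseline = 0.004,  low = 0.001,  high = 0.01,  is_constant = FALSE),
    data.frame(name = "k_off",                 baseline = 0.0048, low = 0.001,  high = 0.01,  is_constant = FALSE),
    data.frame(name = "fdc_secretion",         baseline = 0.18,   low = 0.1,    high = 0.5,   is_constant = FALSE),
    data.frame(name = "rc_secretion",          baseline = 0.18,   low = 0.1,    high = 0.5,   is_constant = FALSE),
    data.frame(name = "decay_rate",            baseline = 0.007,  low = 2e-4,   high = 0.05,  is_constant = FALSE),
    data.frame(name = "diffusion_coeff",       baseline = 7.6,    low = 0,      high = 146,   is_constant = FALSE),
    data.frame(name = "alpha1",                baseline = 0.475,  low = 0,      high = 1,     is_constant = FALSE),
    data.frame(name = "alpha2",                baseline = 3.8,    low = 3.8,    high = 3.8,   is_constant = TRUE)
  )
  rownames(tab) <- tab$name
  tab
}

# Fixed, documented ordering of the 13 emulator/SA inputs. signal_threshold
# is carried in the vector (13th slot) but is a constant of the model; its
# degenerate range is handled explicitly by the design and emulation code.
.sampled_order <- c(
  "r_total", "k_on", "k_off", "k_des", "k_i", "k_r",
  "fdc_secretion", "rc_secretion", "decay_rate", "diffusion_coeff",
  "displacement_constant", "alpha1", "signal_threshold"
)

# Engine settings (lattice, clocks, geometry); not part of the sampled
# biological parameter vector.
.engine_defaults <- function() {
  list(
    grid_spacing   = 10,              # um, lattice voxel edge
    dt_mol         = 1,               # s,  molecular (field/receptor) step
    dt_move        = 15,              # s,  motility step
    duration       = 60,              # min, tracked run length
    burn_in        = 30,              # min, field-only spin-up
    track_interval = 20,              # s,  track sampling interval
    follicle_dims  = c(250, 250, 350),# um, axis-aligned follicle box
    boundary       = "box",           # "box" (reflective) or "ellipsoid"
    n_sectors      = 6,               # surface sampling sectors (+-x,y,z)
    sense_interpolation = TRUE,       # trilinear sub-grid gradient sensing
    knn_k          = 3,               # stromal same-subset k-NN edges
    mrc_band       = 20,              # um, subcapsular MRC shell depth
    secrete_along_edges = TRUE,       # distribute secretion along dendrites
    edge_point_spacing  = 5,          # um, secretion-point interval on edges
    seed           = 1                # default master seed
  )
}

#' Parameter ranges used for sampling and sensitivity analysis
#'
#' Returns the biological parameter table: baseline value, lower and upper
#' sampling bound, and whether the parameter is held constant. Ranges are
#' the ones used by the uncertainty and sensitivity analyses; constants have
#' `low == high`.
#'
#' @param sampled_only if `TRUE`, return only the 13 parameters of the
#'   sampled vector (see [sampled_vector()]), in their frozen order.
#' @return a `data.frame` with columns `name`, `baseline`, `low`, `high`,
#'   `is_constant`.
#' @export
param_ranges <- function(sampled_only = FALSE) {
  tab <- .param_table()
  if (sampled_only) tab <- tab[.sampled_order, ]
  rownames(tab) <- NULL
  tab
}

#' Load and validate simulation parameters
#'
#' Builds the full parameter set from baselines, optionally overridden by a
#' YAML/JSON config file or a named list. Unknown keys are rejected;
#' out-of-range values (negative rates, proportions outside \[0, 1\]) raise
#' an error naming the offending key. `r_total = 0` is valid and encodes the
#' receptor-knockout mode (see [knockout()]).
#'
#' @param config path to a YAML or JSON file, or a named list of overrides;
#'   `NULL` gives all baselines.
#' @param overrides a named list applied after `config` (highest priority),
#'   e.g. from command-line `--param key=value` flags.
#' @return a `simulation_params` object (a validated named list).
#' @examples
#' p <- load_params()
#' p$r_total
#' p2 <- load_params(list(n_bcells = 500, duration = 30))
#' @export
load_params <- function(config = NULL, overrides = list()) {
  tab <- .param_table()
  p <- c(as.list(stats::setNames(tab$baseline, tab$name)), .engine_defaults())

  vals <- list()
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    vals <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::fromJSON(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  } else if (is.list(config)) {
    vals <- config
  } else if (!is.null(config)) {
    stop("config must be a file path, a named list, or NULL")
  }
  vals <- utils::modifyList(vals, overrides)

  if (length(vals)) {
    if (is.null(names(vals)) || any(names(vals) == "")) {
      stop("all config entries must be named")
    }
    unknown <- setdiff(names(vals), names(p))
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    }
    for (k in names(vals)) p[[k]] <- vals[[k]]
  }
  validate_params(p)
}

#' Validate a parameter set
#'
#' Checks non-negativity of all rates and counts, proportions in \[0, 1\],
#' and positivity of the engine clocks and domain. Returns the validated
#' `simulation_params` object (invisibly usable in pipelines).
#'
#' @param p a named list of parameters.
#' @export
validate_params <- function(p) {
  nonneg <- c(
    "cell_diameter", "n_bcells", "n_mrc", "n_fdc", "n_brc",
    "displacement_constant", "signal_threshold", "max_turn_angle",
    "r_total", "k_on", "k_i", "k_des", "k_r", "k_off",
    "fdc_secretion", "rc_secretion", "decay_rate", "diffusion_coeff",
    "alpha1", "alpha2"
  )
  for (k in nonneg) {
    v <- p[[k]]
    if (is.null(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop(k, " out of range")
    }
  }
  if (p$cognate_fraction < 0 || p$cognate_fraction > 1) {
    stop("cognate_fraction out of range")
  }
  for (k in c("grid_spacing", "dt_mol", "dt_move", "duration",
              "track_interval")) {
    if (!is.finite(p[[k]]) || p[[k]] <= 0) stop(k, " out of range")
  }
  if (p$burn_in < 0) stop("burn_in out of range")
  d <- p$follicle_dims
  if (length(d) != 3L || any(!is.finite(d)) || any(d <= 0)) {
    stop("follicle_dims out of range")
  }
  if (!p$boundary %in% c("box", "ellipsoid")) stop("boundary out of range")
  structure(p, class = "simulation_params")
}

#' Extract the 13-parameter sampled vector
#'
#' Returns the ordered vector of the 13 parameters varied by the sensitivity
#' analyses and consumed by the emulator:
#' `r_total, k_on, k_off, k_des, k_i, k_r, fdc_secretion, rc_secretion,
#' decay_rate, diffusion_coeff, displacement_constant, alpha1,
#' signal_threshold`. The ordering is frozen; [vector_to_params()] is its
#' inverse. Engine settings (including the seed) are excluded.
#'
#' @param p a `simulation_params` object.
#' @return a named numeric vector of length 13.
#' @export
sampled_vector <- function(p) {
  stats::setNames(vapply(.sampled_order, function(k) p[[k]], numeric(1)),
                  .sampled_order)
}

#' Rebuild parameters from a sampled vector
#'
#' @param v numeric vector of length 13 in [sampled_vector()] order (names,
#'   if present, are checked).
#' @param base parameter set supplying all non-sampled fields.
#' @return a `simulation_params` object.
#' @export
vector_to_params <- function(v, base = load_params()) {
  if (length(v) != length(.sampled_order)) {
    stop("expected a vector of length ", length(.sampled_order))
  }
  if (!is.null(names(v)) && !identical(names(v), .sampled_order)) {
    stop("vector names do not match the frozen sampled order")
  }
  for (i in seq_along(.sampled_order)) base[[.sampled_order[i]]] <- v[[i]]
  validate_params(base)
}

#' Receptor knockout configuration
#'
#' Returns the parameter set with `r_total = 0`: agents carry no CXCR5, the
#' bound-receptor difference across the cell is always 0 (below any signal
#' threshold), and movement degenerates to the pure persistent random walk.
#'
#' @param p a `simulation_params` object.
#' @export
knockout <- function(p) {
  p$r_total <- 0
  validate_params(p)
}

#' Serialize parameters to YAML or JSON
#'
#' @param p a `simulation_params` object.
#' @param path output path; format chosen by extension (`.json` or `.yaml`).
#' @export
write_params <- function(p, path) {
  x <- unclass(p)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @export
print.simulation_params <- function(x, ...) {
  cat("Simulation parameters (follisim)\n")
  cat(sprintf("  B cells: %g, receptor total: %g, Kd: %.3g nM\n",
              x$n_bcells, x$r_total,
              if (x$k_on > 0) x$k_off / x$k_on * 1e9 else NA_real_))
  cat(sprintf("  Stroma: %g MRC / ~%g FDC / ~%g BRC; secretion %g / %g fg min^-1\n",
              x$n_mrc, x$n_fdc, x$n_brc, x$fdc_secretion, x$rc_secretion))
  cat(sprintf("  Field: D = %g um^2 s^-1, decay = %g s^-1, spacing = %g um\n",
              x$diffusion_coeff, x$decay_rate, x$grid_spacing))
  cat(sprintf("  Run: %g min (+%g min burn-in), dt_mol %g s, dt_move %g s\n",
              x$duration, x$burn_in, x$dt_mol, x$dt_move))
  invisible(x)
}
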