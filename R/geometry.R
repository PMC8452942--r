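# Follicle geometry arithmetic feeding the default domain and cell counts.

#' Follicle volume from whole-node measurements
#'
#' Converts a whole-lymph-node volume to the volume of a single follicle:
#' the node volume (mm^3) is multiplied by the fraction of the node occupied
#' by follicles and divided by the number of follicles, with the result in
#' um^3.
#'
#' @param ln_volume whole-lymph-node volume in mm^3.
#' @param follicular_fraction proportion of node volume occupied by
#'   follicles (0-1).
#' @param n_follicles number of follicles the B-zone is split between.
#' @return single-follicle volume in um^3.
#' @examples
#' follicle_volume(1.25, 0.10, 18)  # popliteal node estimate
#' follicle_volume(2.4, 0.18, 12.5) # inguinal node estimate
#' @export
follicle_volume <- function(ln_volume, follicular_fraction, n_follicles) {
  for (v in list(ln_volume, follicular_fraction, n_follicles)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("all inputs to follicle_volume must be positive numbers")
    }
  }
  ln_volume * 1e9 * follicular_fraction / n_follicles
}

#' Density-matched downscaling of a parameter set
#'
#' Scales the follicle volume and every cell count (B cells and the three
#' stromal subsets) by the same factor, preserving cell densities and
#' therefore the collective ligand-consumption feedback that shapes the
#' chemokine landscape at full scale. Use for desk-scale replicates where
#' density-dependent behaviour (e.g. the knockout scanning contrast) must
#' be retained.
#'
#' @param p a `simulation_params` object.
#' @param scale volume/count scaling factor in (0, 1].
#' @return the scaled `simulation_params`.
#' @export
downscale_params <- function(p, scale) {
  if (scale <= 0 || scale > 1) stop("scale must be in (0, 1]")
  p$n_bcells <- max(1, round(p$n_bcells * scale))
  p$n_mrc <- max(1, round(p$n_mrc * scale))
  p$n_fdc <- max(1, round(p$n_fdc * scale))
  p$n_brc <- max(1, round(p$n_brc * scale))
  p$follicle_dims <- p$follicle_dims * scale^(1 / 3)
  validate_params(p)
}

#' Canonical model follicle specification
#'
#' The simulated domain and its cellularity: a ~250 x 250 x 350 um follicle
#' (spheroidal volume 1.25e7 um^3) holding 4.8e4 measured CD19+ B cells,
#' represented in the model by 6000 agents (an 8-fold density downscaling),
#' with 100 MRC, ~200 FDC and ~450 BRC stromal cells. A density-matched mode
#' shrinks the domain by the same factor so that agent density equals the
#' measured cell density.
#'
#' @param density_matched if `TRUE`, scale the domain volume by the B-cell
#'   downscaling factor so 6000 agents occupy follicular density.
#' @return a list with `dims` (um), `spheroid_volume`, `box_volume`,
#'   `n_bcells_measured`, `n_bcells_model`, `downscale_factor`, and
#'   `stromal_counts`.
#' @export
model_follicle_spec <- function(density_matched = FALSE) {
  dims <- c(250, 250, 350)
  n_meas <- 4.8e4
  n_model <- 6000
  f <- n_meas / n_model
  if (density_matched) dims <- dims / f^(1 / 3)
  list(
    dims = dims,
    spheroid_volume = 1.25e7,
    box_volume = prod(dims),
    n_bcells_measured = n_meas,
    n_bcells_model = n_model,
    downscale_factor = f,
    stromal_counts = c(MRC = 100, FDC = 200, BRC = 450)
  )
}
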