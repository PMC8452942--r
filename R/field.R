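# CXCL13 concentration lattice: point secretion from stromal nodes, explicit
# 7-point-stencil diffusion, first-order decay. Amounts are stored as
# molecules per voxel (double precision); no-flux (reflective) boundaries,
# so pure diffusion conserves mass exactly and decay is the only sink.

#' Create an empty chemokine field
#'
#' @param dims physical domain size in um (length 3).
#' @param spacing voxel edge in um.
#' @param dt_mol molecular timestep in s.
#' @return a `chemokine_field`: list with `grid` (3-D array of molecule
#'   amounts), `spacing`, `dt_mol`, `dims`.
#' @export
chemokine_field <- function(dims = c(250, 250, 350), spacing = 10,
                            dt_mol = 1) {
  if (any(dims <= 0) || spacing <= 0 || dt_mol <= 0) {
    stop("field dimensions, spacing and dt must be positive")
  }
  n <- pmax(1L, as.integer(round(dims / spacing)))
  structure(
    list(grid = array(0, dim = n), spacing = spacing, dt_mol = dt_mol,
         dims = n * spacing),
    class = "chemokine_field"
  )
}

# Sparse no-flux graph Laplacian of the lattice (adjacency minus degree);
# columns sum to zero, so `g + r * (L %*% g)` conserves mass exactly.
.field_laplacian <- function(n) {
  nx <- n[1]; ny <- n[2]; nz <- n[3]
  nv <- nx * ny * nz
  idx <- array(seq_len(nv), dim = n)
  pairs <- list()
  if (nx > 1) {
    pairs[[length(pairs) + 1L]] <-
      cbind(as.vector(idx[-nx, , , drop = FALSE]),
            as.vector(idx[-1, , , drop = FALSE]))
  }
  if (ny > 1) {
    pairs[[length(pairs) + 1L]] <-
      cbind(as.vector(idx[, -ny, , drop = FALSE]),
            as.vector(idx[, -1, , drop = FALSE]))
  }
  if (nz > 1) {
    pairs[[length(pairs) + 1L]] <-
      cbind(as.vector(idx[, , -nz, drop = FALSE]),
            as.vector(idx[, , -1, drop = FALSE]))
  }
  pr <- do.call(rbind, pairs)
  i <- c(pr[, 1], pr[, 2])
  j <- c(pr[, 2], pr[, 1])
  deg <- tabulate(i, nbins = nv)
  Matrix::sparseMatrix(
    i = c(i, seq_len(nv)), j = c(j, seq_len(nv)),
    x = c(rep(1, length(i)), -deg), dims = c(nv, nv)
  )
}

# admissible explicit timestep for 3-D stability: D*dt/dx^2 <= 1/6
.check_stability <- function(D, dt, dx) {
  if (D > 0 && D * dt / dx^2 > 1 / 6) {
    stop(sprintf(
      "diffusion scheme unstable: D*dt/dx^2 = %.4g > 1/6; use dt <= %.4g s",
      D * dt / dx^2, dx^2 / (6 * D)
    ))
  }
  invisible(TRUE)
}

# number of diffusion sub-steps needed to satisfy the stability bound when
# the molecular timestep is clamped rather than rejected
.diffusion_substeps <- function(D, dt, dx) {
  if (D <= 0) return(1L)
  max(1L, as.integer(ceiling(dt / (dx^2 / (6 * D)))))
}

# per-voxel secretion deposits (molecules per molecular step) for a network
.source_amounts <- function(net, f, p) {
  sp <- secretion_points(
    net,
    spacing = if (is.null(p$edge_point_spacing)) 5 else p$edge_point_spacing,
    along_edges = !isFALSE(p$secrete_along_edges)
  )
  pts <- pmin(pmax(as.matrix(sp[, c("x", "y", "z")]), 1e-9),
              matrix(f$dims - 1e-9, nrow(sp), 3, byrow = TRUE))
  per <- rowsum(mass_to_molecules(sp$rate) * f$dt_mol, .voxel_index(pts, f))
  list(idx = as.integer(rownames(per)), amt = as.numeric(per))
}

# map physical points (n x 3, um) to voxel linear indices
.voxel_index <- function(points, f) {
  n <- dim(f$grid)
  ix <- pmin(pmax(floor(points[, 1] / f$spacing), 0), n[1] - 1)
  iy <- pmin(pmax(floor(points[, 2] / f$spacing), 0), n[2] - 1)
  iz <- pmin(pmax(floor(points[, 3] / f$spacing), 0), n[3] - 1)
  as.integer(ix + n[1] * iy + n[1] * n[2] * iz + 1)
}

#' Advance the chemokine field
#'
#' Applies `n_steps` molecular timesteps. Each step, in order: secretion
#' (every stromal node deposits `rate * dt` molecules into its containing
#' voxel), explicit 7-point-stencil diffusion, and exponential decay
#' `exp(-decay_rate * dt)` per voxel. Errors if the explicit scheme's
#' stability condition `D * dt / dx^2 <= 1/6` is violated, naming the
#' admissible timestep.
#'
#' @param f a `chemokine_field`.
#' @param net a `stromal_network` or `NULL` (no secretion).
#' @param p a `simulation_params` object (supplies `diffusion_coeff`,
#'   `decay_rate`).
#' @param n_steps number of molecular steps to apply.
#' @param auto_clamp subdivide the diffusion update into stable sub-steps
#'   instead of erroring when `D * dt / dx^2 > 1/6` (the engine uses this).
#' @return the updated `chemokine_field`.
#' @export
step_field <- function(f, net, p, n_steps = 1, auto_clamp = FALSE) {
  dt <- f$dt_mol
  dx <- f$spacing
  if (auto_clamp) {
    nsub <- .diffusion_substeps(p$diffusion_coeff, dt, dx)
  } else {
    .check_stability(p$diffusion_coeff, dt, dx)
    nsub <- 1L
  }
  lap <- .field_laplacian(dim(f$grid))
  r <- p$diffusion_coeff * (dt / nsub) / dx^2
  dec <- exp(-p$decay_rate * dt)

  src_idx <- integer(0); src_amt <- numeric(0)
  if (!is.null(net)) {
    src <- .source_amounts(net, f, p)
    src_idx <- src$idx
    src_amt <- src$amt
  }

  g <- as.numeric(f$grid)
  for (s in seq_len(n_steps)) {
    if (length(src_idx)) g[src_idx] <- g[src_idx] + src_amt
    if (r > 0) {
      for (ss in seq_len(nsub)) g <- g + r * as.numeric(lap %*% g)
    }
    if (dec < 1) g <- g * dec
  }
  f$grid <- array(g, dim = dim(f$grid))
  f
}

#' Convert a secretion mass rate to molecules per second
#'
#' Bridges the fg min^-1 cell^-1 secretion rates to lattice amounts:
#' `rate * 1e-15 / MW * N_A / 60`, with the CXCL13 molecular weight
#' MW = 10,300 g mol^-1.
#'
#' @param mass_rate secretion rate(s) in fg min^-1.
#' @return molecules s^-1.
#' @examples
#' mass_to_molecules(0.18) # ~175 molecules/s
#' @export
mass_to_molecules <- function(mass_rate) {
  if (any(mass_rate < 0)) stop("mass rate must be non-negative")
  mass_rate * 1e-15 / .CXCL13_MW * .AVOGADRO / 60
}

# molecules-per-voxel -> molar concentration
.voxel_litres <- function(spacing) (spacing^3) * 1e-15 # um^3 -> L
.molecules_to_molar <- function(amount, spacing) {
  amount / (.AVOGADRO * .voxel_litres(spacing))
}

# Trilinear interpolation of voxel-centre amounts at physical points
# (n x 3, um). Sub-grid sampling for gradient sensing: cells are smaller
# than a voxel, so nearest-voxel lookups quantize the perceived gradient to
# lattice steps; interpolation restores a smooth concentration surface.
.interp_amount <- function(g, n, spacing, pts) {
  u <- pts / spacing - 0.5
  i0 <- pmin(pmax(floor(u), 0), matrix(n - 2, nrow(pts), 3, byrow = TRUE))
  i0 <- pmax(i0, 0)
  fr <- pmin(pmax(u - i0, 0), 1)
  v <- 0
  for (dx in 0:1) {
    wx <- if (dx == 1) fr[, 1] else 1 - fr[, 1]
    for (dy in 0:1) {
      wy <- if (dy == 1) fr[, 2] else 1 - fr[, 2]
      for (dz in 0:1) {
        wz <- if (dz == 1) fr[, 3] else 1 - fr[, 3]
        idx <- (i0[, 1] + dx) + n[1] * (i0[, 2] + dy) +
          n[1] * n[2] * (i0[, 3] + dz) + 1
        v <- v + wx * wy * wz * g[idx]
      }
    }
  }
  v
}

#' Concentration at a point, in nM
#'
#' Converts the molecule amount of the voxel containing `point` to molarity:
#' `molecules / (voxel volume in litres) / N_A`, reported in nM.
#'
#' @param f a `chemokine_field`.
#' @param point physical coordinates in um (length 3).
#' @export
concentration_at <- function(f, point) {
  if (length(point) != 3L) stop("point must have 3 coordinates")
  if (any(point < 0) || any(point > f$dims)) {
    stop("point outside the field domain")
  }
  v <- .voxel_index(matrix(point, 1, 3), f)
  .molecules_to_molar(f$grid[v], f$spacing) * 1e9
}

#' Write a field snapshot as long-format CSV
#'
#' One row per voxel: voxel indices, voxel-centre coordinates (um), amount
#' (molecules) and concentration (nM).
#'
#' @param f a `chemokine_field`.
#' @param path output CSV path.
#' @export
write_field_csv <- function(f, path) {
  n <- dim(f$grid)
  ijk <- expand.grid(i = seq_len(n[1]), j = seq_len(n[2]), k = seq_len(n[3]))
  out <- data.frame(
    ijk,
    x = (ijk$i - 0.5) * f$spacing,
    y = (ijk$j - 0.5) * f$spacing,
    z = (ijk$k - 0.5) * f$spacing,
    amount = as.numeric(f$grid),
    conc_nM = .molecules_to_molar(as.numeric(f$grid), f$spacing) * 1e9
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.chemokine_field <- function(x, ...) {
  n <- dim(x$grid)
  cat(sprintf(
    "Chemokine field: %d x %d x %d voxels (%g um spacing), total %.4g molecules (mean %.3g nM)\n",
    n[1], n[2], n[3], x$spacing, sum(x$grid),
    .molecules_to_molar(mean(x$grid), x$spacing) * 1e9
  ))
  invisible(x)
}
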