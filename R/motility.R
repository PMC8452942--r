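# Motility: receptor-occupancy asymmetry across the cell body gates
# chemotaxis. Six surface sectors (cell radius along +-x, +-y, +-z) each
# hold 1/6 of the receptor pool and see their own local concentration; the
# spread between the best- and worst-occupied sector (delta_LR, in bound
# "signaling" receptors) is compared with the signal threshold. Above
# threshold the cell turns towards the occupancy-weighted direction with
# angular spread alpha1 (wrapped-Gaussian, radians); otherwise it performs a
# persistent random walk about its current heading with spread alpha2.
# Every step moves the cell displacement_constant * dt along the new
# heading; the follicle boundary reflects.

.sector_axes <- matrix(c(
  1, 0, 0, -1, 0, 0,
  0, 1, 0, 0, -1, 0,
  0, 0, 1, 0, 0, -1
), ncol = 3, byrow = TRUE)

#' Create a B-cell agent
#'
#' @param p a `simulation_params` object.
#' @param position initial position (um).
#' @param heading initial heading (normalized internally).
#' @return a `bcell_agent`: list with `position`, `heading`, `receptors`
#'   (whole-cell four-state pool, all free initially) and `sector_bound`
#'   (the six per-sector bound counts from the last sensing probe).
#' @export
make_agent <- function(p, position = p$follicle_dims / 2,
                       heading = c(1, 0, 0)) {
  h <- heading / sqrt(sum(heading^2))
  structure(list(position = position, heading = h,
                 receptors = receptor_state(p$r_total),
                 sector_bound = numeric(6)),
            class = "bcell_agent")
}

#' Sense the local chemokine gradient
#'
#' Samples the concentration at the agent's six surface sectors (cell
#' radius along the +-x/y/z axes; trilinear sub-grid interpolation when
#' `p$sense_interpolation` is set) and allocates `r_free / 6` of the
#' cell's current free receptors to each sector. Each sector's bound count
#' is the equilibrium occupancy of its allocation at the sector-local
#' concentration, `(r_free / 6) * L / (L + Kd)` with `Kd = k_off / k_on`.
#' `delta_LR` is the spread between the best and worst sector, and
#' `direction` the normalized sum of the sector axes weighted by bound
#' counts (the agent's current heading when the weighted sum is
#' degenerate, e.g. in a uniform field). The probe is a gradient readout
#' only: ligand mass exchange happens in the whole-cell receptor update
#' ([step_receptors()]), which is also what depletes `r_free` (and hence
#' sensing capacity) under sustained exposure.
#'
#' @param agent a `bcell_agent`.
#' @param f a `chemokine_field`.
#' @param p a `simulation_params` object.
#' @return list with `delta_LR`, `direction` (unit vector), and the updated
#'   `agent` (refreshed `sector_bound`).
#' @export
sense_gradient <- function(agent, f, p) {
  r <- p$cell_diameter / 2
  pts <- sweep(.sector_axes * r, 2, agent$position, "+")
  pts <- pmin(pmax(pts, 1e-9), matrix(f$dims - 1e-9, 6, 3, byrow = TRUE))
  g <- as.numeric(f$grid)
  amt <- if (isTRUE(p$sense_interpolation)) {
    .interp_amount(g, dim(f$grid), f$spacing, pts)
  } else {
    g[.voxel_index(pts, f)]
  }
  L <- .molecules_to_molar(amt, f$spacing)
  Kd <- if (p$k_on > 0) p$k_off / p$k_on else Inf
  occ <- L / (L + Kd)
  occ[!is.finite(occ)] <- 0
  bound <- (agent$receptors[["free"]] / 6) * occ
  agent$sector_bound <- bound
  delta <- max(bound) - min(bound)
  dir <- as.numeric(crossprod(.sector_axes, bound))
  nrm <- sqrt(sum(dir^2))
  direction <- if (nrm > 1e-12) dir / nrm else agent$heading
  list(delta_LR = delta, direction = direction, agent = agent)
}

# Draw new headings about per-row target directions with wrapped-Gaussian
# angular spread sigma (radians), turn clipped to max_turn (radians).
# targets: n x 3 unit rows. Vectorized; uses the session RNG.
.draw_headings <- function(targets, sigma, max_turn) {
  n <- nrow(targets)
  theta <- stats::rnorm(n, 0, sigma)
  theta <- theta - 2 * pi * round(theta / (2 * pi)) # wrap to (-pi, pi]
  theta <- sign(theta) * pmin(abs(theta), max_turn)
  # random unit axis perpendicular to each target
  v <- matrix(stats::rnorm(3 * n), n, 3)
  proj <- rowSums(v * targets)
  u <- v - proj * targets
  un <- sqrt(rowSums(u^2))
  bad <- un < 1e-12
  if (any(bad)) { # degenerate draw: any perpendicular will do
    alt <- cbind(-targets[bad, 2], targets[bad, 1], 0)
    altn <- sqrt(rowSums(alt^2))
    flat <- altn < 1e-12
    alt[flat, ] <- matrix(c(1, 0, 0), sum(flat), 3, byrow = TRUE)
    u[bad, ] <- alt
    un[bad] <- sqrt(rowSums(u[bad, , drop = FALSE]^2))
  }
  u <- u / un
  # rotate target about u (u is perpendicular): h = cos(t)*T + sin(t)*(u x T)
  uxT <- cbind(
    u[, 2] * targets[, 3] - u[, 3] * targets[, 2],
    u[, 3] * targets[, 1] - u[, 1] * targets[, 3],
    u[, 1] * targets[, 2] - u[, 2] * targets[, 1]
  )
  h <- cos(theta) * targets + sin(theta) * uxT
  h / sqrt(rowSums(h^2))
}

# Reflect positions (n x 3) off the box [0, dims]; flips the matching
# heading components. Returns list(pos, head).
.reflect_box <- function(pos, head, dims) {
  for (ax in 1:3) {
    # a step never exceeds the domain size, so one double reflection pass
    # suffices
    lo <- pos[, ax] < 0
    if (any(lo)) {
      pos[lo, ax] <- -pos[lo, ax]
      head[lo, ax] <- -head[lo, ax]
    }
    hi <- pos[, ax] > dims[ax]
    if (any(hi)) {
      pos[hi, ax] <- 2 * dims[ax] - pos[hi, ax]
      head[hi, ax] <- -head[hi, ax]
    }
  }
  list(pos = pos, head = head)
}

#' Advance an agent by one motility step
#'
#' If `delta_LR` meets the signal threshold the new heading is drawn with
#' wrapped-Gaussian angular spread `alpha1` (radians) about the
#' chemotactic target — the normalized sum of the gradient `direction` and
#' the current heading, so cell polarity persists while the gradient
#' steers; otherwise it is drawn about the current heading with spread
#' `alpha2`. The turn is clipped to `max_turn_angle` and the agent
#' advances `displacement_constant * dt` um along the new heading,
#' reflecting off the follicle boundary.
#'
#' @param agent a `bcell_agent`.
#' @param delta_LR,direction output of [sense_gradient()].
#' @param p a `simulation_params` object.
#' @param dt motility step in minutes (default `dt_move / 60`).
#' @return the moved `bcell_agent`.
#' @export
step_move <- function(agent, delta_LR, direction, p, dt = p$dt_move / 60) {
  if (dt <= 0) stop("dt must be positive")
  chemo <- delta_LR >= p$signal_threshold
  target <- if (chemo) {
    blend <- direction + agent$heading
    bn <- sqrt(sum(blend^2))
    if (bn > 1e-9) blend / bn else direction
  } else {
    agent$heading
  }
  sigma <- if (chemo) p$alpha1 else p$alpha2
  h <- .draw_headings(matrix(target, 1, 3), sigma, p$max_turn_angle * pi / 180)
  pos <- matrix(agent$position + p$displacement_constant * dt * h[1, ], 1, 3)
  rb <- .reflect_box(pos, h, p$follicle_dims)
  agent$position <- rb$pos[1, ]
  agent$heading <- rb$head[1, ]
  agent
}
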