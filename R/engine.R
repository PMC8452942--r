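# Run orchestration. Per molecular step (dt_mol), in this fixed order:
# secretion -> diffusion -> decay -> receptor exchange; the motility update
# runs every dt_move seconds and track sampling every track_interval
# seconds. The field is burned in (secretion/diffusion/decay only) before
# agents enter. A run is fully deterministic given (params, seed).

#' Run one simulation
#'
#' Builds the stromal network, burns the chemokine field in to (near)
#' steady state, seeds the B-cell agents uniformly in the follicle with
#' all-free receptors split equally over six surface sectors, then loops
#' molecular and motility updates for `p$duration` minutes, sampling tracks
#' every `p$track_interval` seconds.
#'
#' @param p a `simulation_params` object.
#' @param seed integer seed (defaults to `p$seed`); the run is bit-
#'   reproducible given `(p, seed)`.
#' @param network optional pre-built `stromal_network` (e.g. with
#'   [subset_secretion()] overrides).
#' @param field optional pre-burned `chemokine_field`; skips burn-in.
#'   Sharing one burned field between paired runs (e.g. wild-type vs
#'   knockout at the same seed) avoids recomputing identical spin-ups.
#' @param verbose print per-phase timings.
#' @return a `follisim_run`: list with `params`, `seed`, `times` (min),
#'   `positions` (timepoints x cells x 3), `receptors` (timepoints x cells
#'   x 4 whole-cell pools), `metrics` (per-cell), `summary` (medians/IQR),
#'   `network`, `field` (final state), and `diagnostics` (ligand mass
#'   budget, timings).
#' @export
run_simulation <- function(p, seed = p$seed, network = NULL, field = NULL,
                           verbose = FALSE) {
  p <- validate_params(p)
  set.seed(seed)
  t0 <- proc.time()[["elapsed"]]

  if (is.null(network)) network <- generate_network(p)
  if (is.null(field)) {
    field <- chemokine_field(p$follicle_dims, p$grid_spacing, p$dt_mol)
    burn <- TRUE
  } else burn <- FALSE

  dt <- p$dt_mol
  dx <- field$spacing
  nsub <- .diffusion_substeps(p$diffusion_coeff, dt, dx)
  lap <- .field_laplacian(dim(field$grid))
  rdiff <- p$diffusion_coeff * (dt / nsub) / dx^2
  dec <- exp(-p$decay_rate * dt)
  vox_sp <- field$spacing
  cconst <- 1 / (.AVOGADRO * .voxel_litres(vox_sp))

  src <- .source_amounts(network, field, p)
  src_idx <- src$idx
  src_amt <- src$amt
  g <- as.numeric(field$grid)

  budget <- c(secreted = 0, decayed = 0, captured = 0, released = 0,
              destroyed = 0, clamped = 0, initial = sum(g))

  field_step <- function(g) {
    g[src_idx] <- g[src_idx] + src_amt
    if (rdiff > 0) {
      for (ss in seq_len(nsub)) g <- g + rdiff * as.numeric(lap %*% g)
    }
    if (dec < 1) {
      budget["decayed"] <<- budget["decayed"] + sum(g) * (1 - dec)
      g <- g * dec
    }
    budget["secreted"] <<- budget["secreted"] + sum(src_amt)
    g
  }

  if (burn) {
    for (s in seq_len(round(p$burn_in * 60 / dt))) g <- field_step(g)
  }
  t_burn <- proc.time()[["elapsed"]]

  # --- agents ---------------------------------------------------------
  n <- p$n_bcells
  if (n < 1) stop("n_bcells must be at least 1")
  dims <- p$follicle_dims
  pos <- cbind(stats::runif(n, 0, dims[1]), stats::runif(n, 0, dims[2]),
               stats::runif(n, 0, dims[3]))
  hd <- matrix(stats::rnorm(3 * n), n, 3)
  hd <- hd / sqrt(rowSums(hd^2))

  ko <- p$r_total <= 0
  Rf <- rep(p$r_total, n) # whole-cell pools; sensing probes split r_free/6
  Rb <- numeric(n); Rd <- numeric(n); Ri <- numeric(n)
  crad <- p$cell_diameter / 2

  ngrid <- dim(field$grid)
  interp <- isTRUE(p$sense_interpolation)
  sector_geom <- function(pos) {
    v <- matrix(0L, n, 6)
    pts <- matrix(0, n * 6, 3)
    for (s in 1:6) {
      ps <- sweep(pos, 2, .sector_axes[s, ] * crad, "+")
      ps <- pmin(pmax(ps, 1e-9),
                 matrix(field$dims - 1e-9, n, 3, byrow = TRUE))
      v[, s] <- .voxel_index(ps, field)
      pts[(s - 1) * n + seq_len(n), ] <- ps
    }
    list(vox = v, pts = pts)
  }
  sg <- sector_geom(pos)
  vox <- sg$vox
  spts <- sg$pts
  cvox <- .voxel_index(pos, field)

  total_s <- round(p$duration * 60 / dt)
  rec_every <- round(p$track_interval / dt)
  move_every <- round(p$dt_move / dt)
  nt <- floor(total_s / rec_every) + 1L
  times <- (seq_len(nt) - 1L) * rec_every * dt / 60
  positions <- array(NA_real_, c(nt, n, 3))
  receptors <- array(NA_real_, c(nt, n, 4),
                     dimnames = list(NULL, NULL,
                                     c("free", "bound", "desensitized",
                                       "internalized")))
  record <- function(ti) {
    positions[ti, , ] <<- pos
    receptors[ti, , 1] <<- Rf
    receptors[ti, , 2] <<- Rb
    receptors[ti, , 3] <<- Rd
    receptors[ti, , 4] <<- Ri
  }
  record(1L)

  dt_move_min <- p$dt_move / 60
  step_len <- p$displacement_constant * dt_move_min
  max_turn <- p$max_turn_angle * pi / 180
  ell_c <- dims / 2
  chemo_frac <- numeric(0)

  for (ts in seq_len(total_s)) {
    g <- field_step(g)

    if (!ko) {
      L <- g[cvox] * cconst # whole-cell exchange at the containing voxel
      st <- .rk4_receptors(Rf, Rb, Rd, Ri, L, p, dt)
      Rf <- st$Rf; Rb <- st$Rb; Rd <- st$Rd; Ri <- st$Ri
      budget["captured"] <- budget["captured"] + sum(st$captured)
      budget["released"] <- budget["released"] + sum(st$released)
      budget["destroyed"] <- budget["destroyed"] + sum(st$destroyed)
      flux <- rowsum(st$released - st$captured, cvox)
      ids <- as.integer(rownames(flux))
      g[ids] <- g[ids] + as.numeric(flux)
      neg <- g[ids] < 0
      if (any(neg)) {
        budget["clamped"] <- budget["clamped"] - sum(g[ids][neg])
        g[ids][neg] <- 0
      }
    }

    if (ts %% move_every == 0L) {
      if (!ko) {
        # sensing probe: r_free/6 per sector at equilibrium occupancy of
        # the sector-local concentration (Kd = k_off/k_on)
        amt <- if (interp) .interp_amount(g, ngrid, vox_sp, spts)
        else g[as.vector(vox)]
        Lsec <- matrix(amt * cconst, n, 6)
        Kd <- if (p$k_on > 0) p$k_off / p$k_on else Inf
        occ <- Lsec / (Lsec + Kd)
        occ[!is.finite(occ)] <- 0
        Rbp <- (Rf / 6) * occ
        cols <- lapply(1:6, function(s) Rbp[, s])
        delta <- do.call(pmax, cols) - do.call(pmin, cols)
        dirs <- Rbp %*% .sector_axes
        nrm <- sqrt(rowSums(dirs^2))
        chemo <- delta >= p$signal_threshold & nrm > 1e-12
      } else {
        chemo <- rep(FALSE, n)
      }
      chemo_frac <- c(chemo_frac, mean(chemo))
      targets <- hd
      if (any(chemo)) {
        gdir <- dirs[chemo, , drop = FALSE] / nrm[chemo]
        blend <- gdir + hd[chemo, , drop = FALSE]
        bn <- sqrt(rowSums(blend^2))
        flat <- bn < 1e-9 # gradient exactly opposes heading: steer fully
        blend[flat, ] <- gdir[flat, , drop = FALSE]
        bn[flat] <- 1
        targets[chemo, ] <- blend / bn
      }
      sigma <- ifelse(chemo, p$alpha1, p$alpha2)
      hnew <- .draw_headings(targets, sigma, max_turn)
      pnew <- pos + step_len * hnew
      if (p$boundary == "ellipsoid") {
        rad <- rowSums(((pnew - matrix(ell_c, n, 3, byrow = TRUE)) /
                          matrix(dims / 2, n, 3, byrow = TRUE))^2)
        out <- rad > 1
        pnew[out, ] <- pos[out, , drop = FALSE]
        hnew[out, ] <- -hnew[out, , drop = FALSE]
        pos <- pnew; hd <- hnew
      } else {
        rb <- .reflect_box(pnew, hnew, dims)
        pos <- rb$pos; hd <- rb$head
      }
      sg <- sector_geom(pos)
      vox <- sg$vox
      spts <- sg$pts
      cvox <- .voxel_index(pos, field)
    }

    if (ts %% rec_every == 0L) record(ts %/% rec_every + 1L)
  }
  t_loop <- proc.time()[["elapsed"]]

  metrics <- do.call(rbind, lapply(seq_len(n), function(i) {
    compute_metrics(positions[, i, ], times, vox_sp)
  }))
  metrics <- cbind(cell_id = seq_len(n), metrics)

  field$grid <- array(g, dim = dim(field$grid))
  budget["final"] <- sum(g)
  res <- list(
    params = p, seed = seed, times = times, positions = positions,
    receptors = receptors, metrics = metrics,
    summary = summarize_metrics(metrics[-1]),
    network = network, field = field,
    diagnostics = list(
      mass_budget = budget,
      chemotaxis_fraction = chemo_frac,
      timings = c(burn_in = t_burn - t0, loop = t_loop - t_burn)
    )
  )
  if (verbose) {
    message(sprintf("burn-in %.1fs, loop %.1fs", t_burn - t0,
                    t_loop - t_burn))
  }
  structure(res, class = "follisim_run")
}

#' Burn in a chemokine field for a parameter set
#'
#' Convenience helper producing the pre-agent steady-state field, reusable
#' across paired runs via the `field` argument of [run_simulation()].
#'
#' @inheritParams run_simulation
#' @export
burn_in_field <- function(p, network, verbose = FALSE) {
  f <- chemokine_field(p$follicle_dims, p$grid_spacing, p$dt_mol)
  step_field(f, network, p, n_steps = round(p$burn_in * 60 / p$dt_mol),
             auto_clamp = TRUE)
}

#' Run a batch of replicate simulations
#'
#' Executes `n_runs` replicates with per-run seeds `master_seed + index`
#' and pools the per-run medians of every track metric.
#'
#' @param p a `simulation_params` object.
#' @param n_runs number of replicates (>= 1).
#' @param master_seed base seed.
#' @param keep_runs keep the full `follisim_run` objects (set `FALSE` to
#'   retain only per-run medians for large batches).
#' @return a `follisim_batch`: list with `medians` (runs x metrics
#'   data.frame), `pooled` (median over runs of each per-run median),
#'   `seeds`, and (optionally) `runs`.
#' @export
run_batch <- function(p, n_runs, master_seed = p$seed, keep_runs = TRUE) {
  if (n_runs < 1) stop("n_runs must be at least 1")
  seeds <- master_seed + seq_len(n_runs)
  runs <- vector("list", n_runs)
  med <- NULL
  for (i in seq_len(n_runs)) {
    r <- run_simulation(p, seed = seeds[i])
    m <- vapply(r$metrics[-1], stats::median, numeric(1))
    med <- rbind(med, m)
    if (keep_runs) runs[[i]] <- r
  }
  med <- as.data.frame(med)
  rownames(med) <- NULL
  structure(
    list(medians = med,
         pooled = vapply(med, stats::median, numeric(1)),
         seeds = seeds, runs = if (keep_runs) runs),
    class = "follisim_batch"
  )
}

#' Write tracks to CSV
#'
#' Long format: `cell_id, t, x, y, z, r_free, r_bound, r_des, r_int`.
#'
#' @param run a `follisim_run`.
#' @param path output CSV path.
#' @export
write_tracks <- function(run, path) {
  nt <- length(run$times)
  n <- dim(run$positions)[2]
  out <- data.frame(
    cell_id = rep(seq_len(n), each = nt),
    t = rep(run$times, n),
    x = as.vector(run$positions[, , 1]),
    y = as.vector(run$positions[, , 2]),
    z = as.vector(run$positions[, , 3]),
    r_free = as.vector(run$receptors[, , 1]),
    r_bound = as.vector(run$receptors[, , 2]),
    r_des = as.vector(run$receptors[, , 3]),
    r_int = as.vector(run$receptors[, , 4])
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.follisim_run <- function(x, ...) {
  cat(sprintf(
    "follisim run (seed %s): %d cells, %.0f min tracked at %g s\n",
    format(x$seed), dim(x$positions)[2], max(x$times), x$params$track_interval
  ))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-20s %.3g [%.3g - %.3g]\n", s$metric[i], s$median[i],
                s$q1[i], s$q3[i]))
  }
  invisible(x)
}

#' @export
summary.follisim_run <- function(object, ...) object$summary

#' @export
print.follisim_batch <- function(x, ...) {
  cat(sprintf("follisim batch: %d runs\npooled medians:\n",
              nrow(x$medians)))
  print(round(x$pooled, 4))
  invisible(x)
}
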