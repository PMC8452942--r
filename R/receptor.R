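# Four-state CXCR5 cycle per agent (mean-field ODE, continuous counts):
#
#   dRf/dt = -k_on*L*Rf + k_off*Rb + k_r*Ri      (free surface receptors)
#   dRb/dt =  k_on*L*Rf - (k_off + k_des)*Rb     (ligand-bound, signaling)
#   dRd/dt =  k_des*Rb  - k_i*Rd                 (desensitized, ligand kept)
#   dRi/dt =  k_i*Rd    - k_r*Ri                 (internalized; ligand
#                                                 destroyed at this step)
#
# advanced by one classical RK4 step per molecular timestep with the local
# ligand concentration L (molar) held fixed over the step. The sum of the
# four pools is conserved exactly by construction. Ligand mass accounting
# uses the same RK4 quadrature: captured = int k_on*L*Rf dt, released =
# int k_off*Rb dt, destroyed = int k_i*Rd dt, so that
# delta(Rb + Rd) = captured - released - destroyed to machine precision.

# Vectorized RK4 core. Rf, Rb, Rd, Ri, L are equal-length numerics.
# Returns the new states plus the integrated captured/released/destroyed
# ligand amounts (molecules) over the step.
.rk4_receptors <- function(Rf, Rb, Rd, Ri, L, p, dt) {
  a <- p$k_on * L
  koff <- p$k_off; kdes <- p$k_des; ki <- p$k_i; kr <- p$k_r

  d1f <- -a * Rf + koff * Rb + kr * Ri
  d1b <- a * Rf - (koff + kdes) * Rb
  d1d <- kdes * Rb - ki * Rd
  d1i <- ki * Rd - kr * Ri

  f2 <- Rf + 0.5 * dt * d1f; b2 <- Rb + 0.5 * dt * d1b
  dd2 <- Rd + 0.5 * dt * d1d; i2 <- Ri + 0.5 * dt * d1i
  d2f <- -a * f2 + koff * b2 + kr * i2
  d2b <- a * f2 - (koff + kdes) * b2
  d2d <- kdes * b2 - ki * dd2
  d2i <- ki * dd2 - kr * i2

  f3 <- Rf + 0.5 * dt * d2f; b3 <- Rb + 0.5 * dt * d2b
  dd3 <- Rd + 0.5 * dt * d2d; i3 <- Ri + 0.5 * dt * d2i
  d3f <- -a * f3 + koff * b3 + kr * i3
  d3b <- a * f3 - (koff + kdes) * b3
  d3d <- kdes * b3 - ki * dd3
  d3i <- ki * dd3 - kr * i3

  f4 <- Rf + dt * d3f; b4 <- Rb + dt * d3b
  dd4 <- Rd + dt * d3d; i4 <- Ri + dt * d3i
  d4f <- -a * f4 + koff * b4 + kr * i4
  d4b <- a * f4 - (koff + kdes) * b4
  d4d <- kdes * b4 - ki * dd4
  d4i <- ki * dd4 - kr * i4

  w <- dt / 6
  list(
    Rf = Rf + w * (d1f + 2 * d2f + 2 * d3f + d4f),
    Rb = Rb + w * (d1b + 2 * d2b + 2 * d3b + d4b),
    Rd = Rd + w * (d1d + 2 * d2d + 2 * d3d + d4d),
    Ri = Ri + w * (d1i + 2 * d2i + 2 * d3i + d4i),
    captured = w * a * (Rf + 2 * f2 + 2 * f3 + f4),
    released = w * koff * (Rb + 2 * b2 + 2 * b3 + b4),
    destroyed = w * ki * (Rd + 2 * dd2 + 2 * dd3 + dd4)
  )
}

#' Receptor state constructor
#'
#' @param r_total total receptors; initialised all-free.
#' @return named numeric vector `(free, bound, desensitized, internalized)`.
#' @export
receptor_state <- function(r_total) {
  if (r_total < 0) stop("r_total out of range")
  c(free = r_total, bound = 0, desensitized = 0, internalized = 0)
}

#' Advance the receptor cycle by one timestep
#'
#' One RK4 step of the four-state CXCR5 system at fixed local ligand
#' concentration. Also returns the signed number of ligand molecules to add
#' back to the local voxel: released by unbinding minus captured by binding
#' (ligand on receptors that internalize is destroyed and never returned).
#'
#' @param s receptor state as returned by [receptor_state()].
#' @param local_conc local CXCL13 concentration in M.
#' @param p a `simulation_params` object (rates `k_on`, `k_off`, `k_des`,
#'   `k_i`, `k_r`).
#' @param dt timestep in s (at most the molecular timestep).
#' @return list with `state` (new receptor state) and `ligand_flux`
#'   (molecules, positive = net release to the voxel).
#' @export
step_receptors <- function(s, local_conc, p, dt = p$dt_mol) {
  if (local_conc < 0) stop("negative ligand concentration")
  r <- .rk4_receptors(s[["free"]], s[["bound"]], s[["desensitized"]],
                      s[["internalized"]], local_conc, p, dt)
  list(
    state = c(free = r$Rf, bound = r$Rb, desensitized = r$Rd,
              internalized = r$Ri),
    ligand_flux = r$released - r$captured
  )
}
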