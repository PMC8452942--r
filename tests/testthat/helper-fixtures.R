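# Shared fixtures: small parameter sets and analytic oracles used across
# test files. Everything is generated in code; no stored data.

# a fast, small but physically sensible configuration: density-matched
# miniature follicle
tiny_params <- function(...) {
  p <- downscale_params(load_params(), 100 / 6000)
  p$duration <- 10
  p$burn_in <- 5
  over <- list(...)
  for (k in names(over)) p[[k]] <- over[[k]]
  validate_params(p)
}

# analytic steady state of the four-state receptor cycle at fixed ligand
# concentration (null space of the rate matrix + conservation)
receptor_steady_state <- function(p, L, r_total = p$r_total) {
  a <- p$k_on * L
  M <- rbind(
    c(-a, p$k_off, 0, p$k_r),
    c(a, -(p$k_off + p$k_des), 0, 0),
    c(0, p$k_des, -p$k_i, 0),
    c(1, 1, 1, 1)
  )
  stats::setNames(solve(M, c(0, 0, 0, r_total)),
                  c("free", "bound", "desensitized", "internalized"))
}

# 2-D hypervolume (minimization) against a reference point
hypervolume_2d <- function(pts, ref) {
  pts <- as.matrix(pts)
  pts <- pts[pts[, 1] <= ref[1] & pts[, 2] <= ref[2], , drop = FALSE]
  if (!nrow(pts)) return(0)
  pts <- pts[order(pts[, 1]), , drop = FALSE]
  h <- 0
  prev <- ref[2]
  for (i in seq_len(nrow(pts))) {
    h <- h + (ref[1] - pts[i, 1]) * max(0, prev - pts[i, 2])
    prev <- min(prev, pts[i, 2])
  }
  h
}

# random 3-D rotation matrix
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(
    a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
    2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
    2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2
  ), 3, 3, byrow = TRUE)
}
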