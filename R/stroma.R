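# Stochastic follicular stromal network: the CXCL13 source set.
#
# Three spatial compartments inside the follicle box (z axis points from the
# follicle base towards the subcapsular sinus at z = dims[3]):
#   MRC - shell within `mrc_band` um of the subcapsular (top) face,
#   FDC - central third of the follicle (central box),
#   BRC - outer follicle: outside the FDC core and below the MRC band.
# Node positions are a zoned Poisson point process; edges join each node to
# its k nearest same-subset neighbours (visualization/extension only; only
# nodes secrete).

#' Generate a follicular stromal network
#'
#' Places MRC, FDC and BRC nodes in their spatial compartments and joins
#' each node to its `knn_k` nearest same-subset neighbours. The MRC count is
#' fixed at `p$n_mrc`; FDC and BRC counts are Poisson with means `p$n_fdc`
#' and `p$n_brc` (stochastic network formation). FDC nodes secrete at
#' `p$fdc_secretion`, reticular cells (MRC, BRC) at `p$rc_secretion`
#' (fg min^-1 cell^-1).
#'
#' @param p a `simulation_params` object.
#' @param seed integer RNG seed (`NULL` uses the current RNG state).
#' @return a `stromal_network`: list with `nodes` (data.frame `id`,
#'   `subset`, `x`, `y`, `z`, `secretion_rate`) and `edges` (data.frame
#'   `from`, `to`).
#' @examples
#' net <- generate_network(load_params(), seed = 1)
#' table(net$nodes$subset)
#' @export
generate_network <- function(p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- p$follicle_dims
  if (any(d <= 0) || prod(d) == 0) stop("follicle has zero volume")
  band <- min(p$mrc_band, d[3])
  core_lo <- d / 3
  core_hi <- 2 * d / 3
  if (d[3] - band <= 0 && (p$n_brc > 0 || p$n_fdc > 0)) {
    stop("follicle too small to host the stromal compartments")
  }

  n_fdc <- stats::rpois(1, p$n_fdc)
  n_brc <- stats::rpois(1, p$n_brc)
  n_mrc <- p$n_mrc

  # crude capacity check: one node per (cell_diameter)^3 at most
  cap <- prod(d) / max(p$cell_diameter, 1)^3
  if (n_mrc + n_fdc + n_brc > cap) {
    stop("follicle too small to host the requested stromal counts")
  }

  unif_box <- function(n, lo, hi) {
    cbind(stats::runif(n, lo[1], hi[1]),
          stats::runif(n, lo[2], hi[2]),
          stats::runif(n, lo[3], hi[3]))
  }
  mrc <- unif_box(n_mrc, c(0, 0, d[3] - band), d)
  fdc <- unif_box(n_fdc, core_lo, core_hi)
  # BRC: rejection-sample the outer follicle (below the MRC band, outside
  # the FDC core box)
  brc <- matrix(numeric(0), 0, 3)
  while (nrow(brc) < n_brc) {
    m <- unif_box(2 * (n_brc - nrow(brc)) + 10, c(0, 0, 0),
                  c(d[1], d[2], d[3] - band))
    in_core <- m[, 1] > core_lo[1] & m[, 1] < core_hi[1] &
      m[, 2] > core_lo[2] & m[, 2] < core_hi[2] &
      m[, 3] > core_lo[3] & m[, 3] < core_hi[3]
    brc <- rbind(brc, m[!in_core, , drop = FALSE])
  }
  brc <- brc[seq_len(n_brc), , drop = FALSE]

  pos <- rbind(mrc, fdc, brc)
  subset <- c(rep("MRC", n_mrc), rep("FDC", n_fdc), rep("BRC", n_brc))
  rate <- ifelse(subset == "FDC", p$fdc_secretion, p$rc_secretion)
  nodes <- data.frame(
    id = seq_len(nrow(pos)), subset = subset,
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    secretion_rate = rate, stringsAsFactors = FALSE
  )

  edges <- do.call(rbind, lapply(unique(subset), function(s) {
    idx <- which(subset == s)
    if (length(idx) < 2) return(NULL)
    k <- min(p$knn_k, length(idx) - 1)
    dm <- as.matrix(stats::dist(pos[idx, , drop = FALSE]))
    diag(dm) <- Inf
    from <- rep(idx, each = k)
    to <- idx[as.vector(apply(dm, 1, function(r) order(r)[seq_len(k)]))]
    cbind(pmin(from, to), pmax(from, to))
  }))
  if (is.null(edges)) {
    edges <- data.frame(from = integer(0), to = integer(0))
  } else {
    edges <- unique(data.frame(from = edges[, 1], to = edges[, 2]))
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges), class = "stromal_network")
}

#' Override per-subset secretion rates
#'
#' Returns the network with the secretion rate of each named subset
#' replaced, e.g. to impose reporter-intensity-derived secretion profiles or
#' one-at-a-time secretion perturbations.
#'
#' @param net a `stromal_network`.
#' @param rates named numeric vector or list, names among `"MRC"`, `"FDC"`,
#'   `"BRC"`, values in fg min^-1 cell^-1.
#' @export
subset_secretion <- function(net, rates) {
  rates <- unlist(rates)
  if (is.null(names(rates)) || any(names(rates) == "")) {
    stop("rates must be named by subset")
  }
  unknown <- setdiff(names(rates), c("MRC", "FDC", "BRC"))
  if (length(unknown)) stop("unknown subset: ", paste(unknown, collapse = ", "))
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("secretion rates must be non-negative")
  }
  for (s in names(rates)) {
    net$nodes$secretion_rate[net$nodes$subset == s] <- rates[[s]]
  }
  net
}

#' Secretion point set of a stromal network
#'
#' Distributes each node's secretion along its dendritic processes: the
#' node's rate is split evenly over the node itself plus interpolated
#' points (every `spacing` um) on its incident edges, conserving the total
#' secreted mass. With `along_edges = FALSE` only the node positions
#' secrete. The connected secreting web is what shapes the ridged CXCL13
#' landscape that B cells travel along.
#'
#' @param net a `stromal_network`.
#' @param spacing interpolation interval along edges (um).
#' @param along_edges distribute along edges (default) or nodes only.
#' @return data.frame `(x, y, z, rate)` with `sum(rate)` equal to the total
#'   node secretion.
#' @export
secretion_points <- function(net, spacing = 5, along_edges = TRUE) {
  nd <- net$nodes
  if (!along_edges || !nrow(net$edges)) {
    return(data.frame(x = nd$x, y = nd$y, z = nd$z,
                      rate = nd$secretion_rate))
  }
  eg <- net$edges
  a <- as.matrix(nd[eg$from, c("x", "y", "z")])
  b <- as.matrix(nd[eg$to, c("x", "y", "z")])
  len <- sqrt(rowSums((b - a)^2))
  npts <- pmax(1L, ceiling(len / spacing))
  owner <- rep(eg$from, npts)
  tt <- unlist(lapply(npts, function(k) (seq_len(k) - 0.5) / k))
  rows <- rep(seq_len(nrow(eg)), npts)
  pts <- a[rows, , drop = FALSE] + tt * (b[rows, , drop = FALSE] -
                                           a[rows, , drop = FALSE])
  # each node's rate is shared over its own position + its edge points
  n_owned <- tabulate(owner, nbins = nrow(nd))
  rate_per <- nd$secretion_rate / (n_owned + 1)
  data.frame(
    x = c(nd$x, pts[, 1]), y = c(nd$y, pts[, 2]), z = c(nd$z, pts[, 3]),
    rate = c(rate_per, rate_per[owner])
  )
}

#' Write / read a stromal network as CSV
#'
#' Writes `<prefix>_nodes.csv` (id, subset, x, y, z, secretion_rate) and
#' `<prefix>_edges.csv` (from, to).
#'
#' @param net a `stromal_network`.
#' @param prefix output path prefix.
#' @export
write_network <- function(net, prefix) {
  utils::write.csv(net$nodes, paste0(prefix, "_nodes.csv"), row.names = FALSE)
  utils::write.csv(net$edges, paste0(prefix, "_edges.csv"), row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_network
#' @export
read_network <- function(prefix) {
  nodes <- utils::read.csv(paste0(prefix, "_nodes.csv"),
                           stringsAsFactors = FALSE)
  edges <- utils::read.csv(paste0(prefix, "_edges.csv"))
  structure(list(nodes = nodes, edges = edges), class = "stromal_network")
}

#' Export a stromal network to GraphML
#'
#' Requires the `igraph` package.
#'
#' @param net a `stromal_network`.
#' @param path output `.graphml` path.
#' @export
export_graphml <- function(net, path) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("igraph is required for GraphML export")
  }
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @export
print.stromal_network <- function(x, ...) {
  tb <- table(x$nodes$subset)
  cat(sprintf("Stromal network: %d nodes (%s), %d edges\n",
              nrow(x$nodes),
              paste(sprintf("%s=%d", names(tb), as.integer(tb)),
                    collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}
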