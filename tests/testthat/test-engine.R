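test_that("runs are bit-reproducible given (params, seed)", {
  p <- tiny_params()
  r1 <- run_simulation(p, seed = 3)
  r2 <- run_simulation(p, seed = 3)
  expect_identical(r1$positions, r2$positions)
  expect_identical(r1$receptors, r2$receptors)
  expect_identical(r1$field$grid, r2$field$grid)
  r3 <- run_simulation(p, seed = 4)
  expect_false(identical(r1$positions, r3$positions))
})

test_that("a single-cell run produces exactly one finite track", {
  p <- tiny_params(n_bcells = 1)
  r <- run_simulation(p, seed = 1)
  expect_equal(dim(r$positions)[2], 1)
  expect_equal(nrow(r$metrics), 1)
  expect_true(all(is.finite(unlist(r$metrics))))
})

test_that("wild-type smoke run yields finite, nonzero behaviour metrics", {
  p <- tiny_params(duration = 15)
  r <- run_simulation(p, seed = 2)
  s <- r$summary
  expect_true(all(is.finite(s$median)))
  for (k in c("total_displacement", "net_displacement", "velocity",
              "motility_coefficient", "scanning_rate")) {
    expect_gt(s$median[s$metric == k], 0)
  }
  # track clock: sampled every 20 s for the configured duration
  expect_equal(length(r$times), 15 * 3 + 1)
  expect_equal(max(r$times), 15)
})

test_that("receptor pools stay conserved along every recorded track", {
  p <- tiny_params(duration = 8)
  r <- run_simulation(p, seed = 6)
  totals <- r$receptors[, , 1] + r$receptors[, , 2] + r$receptors[, , 3] +
    r$receptors[, , 4]
  expect_lt(max(abs(totals - p$r_total)) / p$r_total, 1e-6)
  # knockout: receptor track is an all-zero vector
  rk <- run_simulation(knockout(p), seed = 6)
  expect_true(all(rk$receptors == 0))
})

test_that("the ligand mass budget closes", {
  p <- tiny_params(duration = 8)
  r <- run_simulation(p, seed = 7)
  b <- r$diagnostics$mass_budget
  resid <- b[["initial"]] + b[["secreted"]] - b[["decayed"]] +
    b[["released"]] - b[["captured"]] + b[["clamped"]] - b[["final"]]
  expect_lt(abs(resid) / b[["final"]], 1e-6)
})

test_that("batches pool per-run medians with derived seeds", {
  p <- tiny_params(duration = 6)
  b1 <- run_batch(p, 1, master_seed = 10)
  expect_equal(b1$seeds, 11)
  r <- run_simulation(p, seed = 11)
  expect_equal(unname(b1$pooled["velocity"]), median(r$metrics$velocity))
  b3 <- run_batch(p, 3, master_seed = 10, keep_runs = FALSE)
  expect_equal(nrow(b3$medians), 3)
  expect_equal(b3$seeds, 11:13)
  expect_null(b3$runs)
  expect_equal(unname(b3$pooled["scanning_rate"]),
               median(b3$medians$scanning_rate))
  # medians are invariant to run order
  expect_equal(unname(vapply(b3$medians[3:1, ], median, numeric(1))),
               unname(b3$pooled))
})

test_that("pre-built networks and burned fields are honoured", {
  p <- tiny_params(duration = 6)
  set.seed(42)
  net <- generate_network(p)
  f <- burn_in_field(p, net)
  r <- run_simulation(p, seed = 5, network = net, field = f)
  expect_identical(r$network, net)
  # paired wild-type/knockout runs share the same environment
  rk <- run_simulation(knockout(p), seed = 5, network = net, field = f)
  expect_identical(rk$network, net)
})

test_that("tracks and summaries export to disk", {
  p <- tiny_params(n_bcells = 3, duration = 4)
  r <- run_simulation(p, seed = 1)
  path <- file.path(tempdir(), "tracks.csv")
  write_tracks(r, path)
  tab <- read.csv(path)
  expect_equal(nrow(tab), 3 * length(r$times))
  expect_true(all(c("cell_id", "t", "x", "r_bound") %in% names(tab)))
  write_run_summary(r, file.path(tempdir(), "run"))
  js <- jsonlite::read_json(file.path(tempdir(), "run_summary.json"))
  expect_true("velocity" %in% names(js))
})
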