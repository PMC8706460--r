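# Trajectory demultiplexing, RMSD, distance PCA, statistics, diagnostics.

# hand-built two-replica run: one swap accepted between frames 2 and 3
two_replica_run <- function() {
  coords <- lapply(1:8, function(i) matrix(i, 2, 3))
  structure(list(
    frames = list(coords = coords,
                  sweep = rep(c(100, 200, 300, 400), each = 2)[c(1, 2, 3, 4, 5, 6, 7, 8)],
                  replica = rep(1:2, 4),
                  param = c(1, 2, 1, 2, 2, 1, 2, 1),
                  E_scaled = as.numeric(1:8)),
    exchange_log = data.frame(phase = 1:4, sweep = c(100, 200, 300, 400),
                              pair = 1L, replica_a = c(1, 1, 2, 2),
                              replica_b = c(2, 2, 1, 1),
                              delta = 0, accepted = c(FALSE, TRUE, FALSE, FALSE)),
    mapping_history = matrix(c(1, 2, 1, 2, 2, 1, 2, 1, 2, 1), 5, 2,
                             byrow = TRUE),
    config = list(M = 2L)), class = "grest_run")
}

test_that("sorting demultiplexes frames by rung and conserves every frame", {
  run <- two_replica_run()
  srt <- sort_by_parameter(run)
  # rung-1 stream: replica 1 for frames 1-2, replica 2 afterwards
  expect_equal(srt$m1$replica, c(1, 1, 2, 2))
  expect_equal(srt$m2$replica, c(2, 2, 1, 1))
  ids <- c(vapply(srt$m1$coords, function(m) m[1, 1], numeric(1)),
           vapply(srt$m2$coords, function(m) m[1, 1], numeric(1)))
  expect_setequal(ids, 1:8)
  expect_equal(length(srt$m1$sweep), length(srt$m2$sweep))

  # a real run: every frame appears exactly once across rungs
  ml <- ml_fixture()
  real <- run_grest(ml$system, ml$sel, geometric_ladder(3, 1, 5),
                    n_sweeps = 1200, exchange_interval = 200, mode = "mc",
                    seed = 41)
  srt2 <- sort_by_parameter(real)
  per_rung <- vapply(srt2, function(s) length(s$coords), integer(1))
  expect_equal(unname(per_rung), rep(length(real$frames$coords) / 3L, 3L))
})

test_that("no accepted exchanges means sorted streams equal raw replica trajectories", {
  run <- two_replica_run()
  run$exchange_log$accepted[] <- FALSE
  run$frames$param <- rep(1:2, 4)
  srt <- sort_by_parameter(run)
  expect_equal(srt$m1$replica, rep(1L, 4))
  expect_equal(srt$m2$replica, rep(2L, 4))
})

test_that("RMSD is zero under identity and rigid motion, and matches the brute-force oracle", {
  set.seed(12)
  ref <- matrix(rnorm(30), 10, 3)
  expect_equal(rmsd_traj(ref, ref), 0, tolerance = 1e-12)

  ang <- 0.83
  R <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  moved <- ref %*% t(R) + matrix(c(1, -2, 0.5), 10, 3, byrow = TRUE)
  expect_lt(rmsd_traj(moved, ref), 1e-10)

  # printed 4-point fixture against the rotation-grid + polish oracle
  a <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1.2, 0, 0.3, 0.4, 1.1), 4, 3,
              byrow = TRUE)
  b <- matrix(c(0.1, 0, 0, 1.1, 0.2, 0, -0.2, 1.0, 0.3, 0.5, 0.5, 0.9),
              4, 3, byrow = TRUE)
  expect_equal(rmsd_traj(b, a), oracle_rmsd(b, a), tolerance = 1e-6)

  # symmetry when fit and rmsd selections coincide
  expect_equal(rmsd_traj(b, a), rmsd_traj(a, b), tolerance = 1e-9)

  collinear <- cbind(seq_len(5), 0, 0)
  expect_error(rmsd_traj(collinear, collinear), "collinear")
  expect_error(rmsd_traj(b, a, fit_selection = 1:2), "at least 3")
})

test_that("fit and rmsd selections are independent", {
  ml <- ml_fixture()
  r_loop <- rmsd_traj(ml$start, ml$reference,
                      fit_selection = ml$framework_atoms,
                      rmsd_selection = ml$loop_atoms)
  r_fw <- rmsd_traj(ml$start, ml$reference,
                    fit_selection = ml$framework_atoms,
                    rmsd_selection = ml$framework_atoms)
  expect_gt(r_loop, 0.2)
  expect_lt(r_fw, 0.1)
})

test_that("distance-matrix PCA separates constructed clusters and keeps eigen identities", {
  set.seed(30)
  base1 <- matrix(rnorm(24), 8, 3)
  base2 <- base1; base2[5:8, ] <- base2[5:8, ] + 1.5
  frames <- c(lapply(1:40, function(i) base1 + matrix(rnorm(24, sd = 0.03), 8, 3)),
              lapply(1:40, function(i) base2 + matrix(rnorm(24, sd = 0.03), 8, 3)))
  pc <- distance_matrix_pca(frames, 1:8, n_components = 3)
  lab <- rep(1:2, each = 40)
  gap <- abs(mean(pc$scores[lab == 1, 1]) - mean(pc$scores[lab == 2, 1]))
  spread <- max(sd(pc$scores[lab == 1, 1]), sd(pc$scores[lab == 2, 1]))
  expect_gt(gap, 5 * spread)

  # eigenvalue sum equals total feature variance; scores orthogonal
  feats <- t(vapply(frames, function(fr) as.vector(dist(fr[1:8, ])),
                    numeric(28)))
  expect_equal(sum(pc$eigenvalues), sum(apply(feats, 2, var)),
               tolerance = 1e-8)
  cr <- crossprod(pc$scores)
  expect_lt(max(abs(cr[upper.tri(cr)])), 1e-8 * max(diag(cr)))
  expect_true(all(diff(pc$eigenvalues) <= 1e-12))

  # constant trajectory: all variance zero, request truncated with warning
  const <- lapply(1:5, function(i) base1)
  expect_warning(pc0 <- distance_matrix_pca(const, 1:8, 2), "rank")
  expect_equal(max(abs(pc0$scores)), 0, tolerance = 1e-10)
  expect_equal(max(pc0$eigenvalues), 0, tolerance = 1e-20)
})

test_that("exchange statistics count ratios, paths and round trips", {
  empty <- data.frame(phase = integer(), sweep = integer(), pair = integer(),
                      replica_a = integer(), replica_b = integer(),
                      delta = numeric(), accepted = logical())
  st0 <- exchange_statistics(empty, mapping_history = matrix(1:3, 1))
  expect_equal(st0$pairs$attempts, c(0L, 0L))
  expect_true(all(is.na(st0$pairs$ratio)))

  log <- data.frame(phase = 1:10, sweep = 1:10, pair = 1L,
                    replica_a = 1L, replica_b = 2L, delta = 0,
                    accepted = rep(c(TRUE, FALSE), c(3, 7)))
  st <- exchange_statistics(log, mapping_history = matrix(rep(1:2, 11), 11, 2,
                                                          byrow = TRUE))
  expect_equal(st$pairs$ratio[1], 0.3)

  # round trips: rung path 1 -> M -> 1 twice; a path never reaching M: zero
  mh <- cbind(c(1, 2, 3, 2, 1, 3, 1, 2, 1),
              c(3, 2, 1, 2, 3, 1, 3, 2, 2),
              c(2, 1, 2, 1, 2, 2, 2, 1, 3))
  st2 <- exchange_statistics(log[0, ], mapping_history = mh)
  expect_equal(unname(st2$round_trips), c(2L, 1L, 0L))
})

test_that("energy-RMSD diagnostic reports exact, null, and degenerate correlations", {
  set.seed(77)
  ref <- matrix(rnorm(24), 8, 3)
  frames <- lapply(1:400, function(i) ref + matrix(rnorm(24, sd = 0.2), 8, 3))
  r <- rmsd_traj(frames, ref)
  stream <- list(coords = frames, E_scaled = 3 * r + 1)
  co <- energy_rmsd_correlation(stream, ref)
  expect_equal(co$pearson_r, 1, tolerance = 1e-12)

  stream_null <- list(coords = frames, E_scaled = rnorm(400))
  co_null <- energy_rmsd_correlation(stream_null, ref)
  expect_lt(abs(co_null$pearson_r), 0.15)

  stream_flat <- list(coords = frames, E_scaled = rep(2, 400))
  co_flat <- energy_rmsd_correlation(stream_flat, ref)
  expect_true(co_flat$undefined)
  expect_true(is.na(co_flat$pearson_r))
})

test_that("dihedral measurement and well-transition counting agree with construction", {
  ml <- ml_fixture()
  expect_lt(abs(measure_dihedral(ml$start, ml$loop_dihedral)), pi / 2)
  expect_gt(abs(measure_dihedral(ml$reference, ml$loop_dihedral)), pi / 2)
  phi <- c(0.1, -0.2, 3.0, 3.1, -3.0, 0.05, 0.2)
  # cis cis trans trans trans cis cis -> 2 transitions
  expect_equal(count_well_transitions(phi), 2L)
  expect_equal(count_well_transitions(numeric(0)), 0L)
})
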