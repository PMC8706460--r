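# Exchange criterion, propagation, and the replica-exchange driver.

test_that("exchange delta reproduces hand-evaluated and degenerate cases", {
  da <- structure(list(E_uu = 3, uv = data.frame(term_id = "a", E = 2,
                                                 k = 1, l = 2), E_vv = 9),
                  class = "energy_decomposition")
  db <- structure(list(E_uu = 5, uv = data.frame(term_id = "a", E = 4,
                                                 k = 1, l = 2), E_vv = 1),
                  class = "energy_decomposition")
  # (0.8-1)(3-5) + 1^(1/2) (sqrt(0.8)-1)(2-4)
  expect_equal(exchange_delta(da, db, 1, 0.8, 1),
               0.4 + (sqrt(0.8) - 1) * (-2), tolerance = 1e-12)
  expect_equal(exchange_delta(da, db, 1, 0.8, 1), 0.6111456, tolerance = 1e-6)
  expect_equal(exchange_delta(da, db, 0.7, 0.7, 1), 0)

  db_bad <- db; db_bad$uv$term_id <- "b"
  expect_error(exchange_delta(da, db_bad, 1, 0.8, 1), "not aligned")
})

test_that("the gREST delta reduces to REST2 and T-REMD limits exactly", {
  for (seed in 1:8) {
    set.seed(seed)
    bm <- runif(1, 0.5, 1); bn <- bm * runif(1, 0.5, 0.99); b0 <- bm
    # REST2 limit: every cross term has exponent k/l = 1/2
    da <- random_decomposition(seed, n_uv = 4, kl = c(1, 2))
    db <- random_decomposition(seed + 100, n_uv = 4, kl = c(1, 2))
    rest2 <- (bn - bm) * (da$E_uu - db$E_uu) +
      sqrt(b0) * (sqrt(bn) - sqrt(bm)) * (sum(da$uv$E) - sum(db$uv$E))
    expect_equal(exchange_delta(da, db, bm, bn, b0), rest2, tolerance = 1e-12)

    # T-REMD limit: whole system tempered, no cross terms; E_vv cancels
    dta <- structure(list(E_uu = rnorm(1, 0, 4),
                          uv = da$uv[0, ], E_vv = rnorm(1)),
                     class = "energy_decomposition")
    dtb <- structure(list(E_uu = rnorm(1, 0, 4),
                          uv = da$uv[0, ], E_vv = rnorm(1)),
                     class = "energy_decomposition")
    expect_equal(exchange_delta(dta, dtb, bm, bn, b0),
                 (bn - bm) * (dta$E_uu - dtb$E_uu), tolerance = 1e-12)
  }
})

test_that("whole-system selection makes the delta a pure total-energy difference", {
  sys <- random_system(21)
  sel <- solute_selection(seq_len(sys$n_atoms), "all")
  set.seed(1)
  xa <- sys$positions + matrix(rnorm(3 * sys$n_atoms, sd = 0.05), sys$n_atoms)
  xb <- sys$positions + matrix(rnorm(3 * sys$n_atoms, sd = 0.05), sys$n_atoms)
  da <- decompose_energy(sys, sel, xa)
  db <- decompose_energy(sys, sel, xb)
  # scalable categories all fully inside -> Delta = (bn-bm) * dE of those
  expect_equal(nrow(da$uv), 0L)
  expect_equal(exchange_delta(da, db, 1, 0.6, 1),
               (0.6 - 1) * (da$E_uu - db$E_uu), tolerance = 1e-12)
})

test_that("Metropolis criterion accepts all non-positive deltas and calibrates at ln 2", {
  expect_equal(exchange_probability(0), 1)
  expect_equal(exchange_probability(-3.7), 1)
  expect_equal(exchange_probability(2), exp(-2))
  for (d in c(-10, -1, -1e-12, 0)) expect_true(metropolis_accept(d))

  set.seed(42)
  acc <- mean(vapply(seq_len(1e5), function(i) metropolis_accept(log(2)),
                     logical(1)))
  se <- sqrt(0.5 * 0.5 / 1e5)
  expect_lt(abs(acc - 0.5), 3 * se)
})

test_that("accepting a non-positive delta consumes no random draw", {
  set.seed(7); before <- .Random.seed
  metropolis_accept(-1); metropolis_accept(0)
  expect_identical(.Random.seed, before)
  metropolis_accept(0.5)
  expect_false(identical(.Random.seed, before))
})

test_that("a replica at a potential minimum stays put at zero temperature", {
  hb <- make_harmonic_bath(2, 1)
  for (mode in c("mc", "langevin")) {
    res <- propagate(hb$system, hb$sel, x = hb$system$positions,
                     beta_m = Inf, beta_0 = Inf, n_steps = 50, mode = mode,
                     velocities = matrix(0, 3, 3), seed = 5)
    expect_equal(res$x, hb$system$positions, tolerance = 1e-12)
  }
})

test_that("both samplers reproduce the harmonic positional variance T/k", {
  k <- 2; temp <- 1
  hb <- make_harmonic_bath(1, 0, k_solute = k)
  lad <- parameter_ladder(1 / temp, 1 / temp)
  for (mode in c("mc", "langevin")) {
    run <- run_grest(hb$system, hb$sel, lad, n_sweeps = 60000,
                     exchange_interval = 1000, record_interval = 50,
                     mode = mode, step_sd = 1.2, dt = 0.02, friction = 1,
                     seed = 15)
    xs <- vapply(run$frames$coords, function(m) m[1, 1], numeric(1))
    v <- var(xs)
    # sampling error of the variance of ~iid Gaussian draws
    se <- (temp / k) * sqrt(2 / (length(xs) - 1))
    expect_lt(abs(v - temp / k), 4 * se)
  }
})

test_that("a single-replica run reproduces plain propagation and logs no exchanges", {
  hb <- make_harmonic_bath(2, 0)
  lad <- parameter_ladder(1, 1)
  run <- run_grest(hb$system, hb$sel, lad, n_sweeps = 400,
                   exchange_interval = 100, mode = "mc", step_sd = 1,
                   seed = 9)
  expect_equal(nrow(run$exchange_log), 0L)
  # chunk seeds are (seed, replica, chunk); replay them through propagate()
  x <- hb$system$positions
  for (chunk in 1:4)
    x <- propagate(hb$system, hb$sel, x, n_steps = 100, mode = "mc",
                   step_sd = 1, seed = c(9L, 1L, chunk))$x
  expect_equal(run$frames$coords[[4]], x, tolerance = 1e-14)
})

test_that("runs are bit-reproducible from the seed and mappings stay bijective", {
  ml <- ml_fixture()
  lad <- geometric_ladder(4, 1, 5)
  r1 <- run_grest(ml$system, ml$sel, lad, n_sweeps = 2000,
                  exchange_interval = 200, mode = "mc", seed = 33)
  r2 <- run_grest(ml$system, ml$sel, lad, n_sweeps = 2000,
                  exchange_interval = 200, mode = "mc", seed = 33)
  expect_identical(r1$frames$coords, r2$frames$coords)
  expect_identical(r1$exchange_log, r2$exchange_log)
  expect_gt(sum(r1$exchange_log$accepted), 0)
  for (row in seq_len(nrow(r1$mapping_history)))
    expect_setequal(r1$mapping_history[row, ], 1:4)
})

test_that("whole-solute gREST acceptance matches closed-form T-REMD theory", {
  hb <- make_harmonic_bath(2, 2)
  lad <- parameter_ladder(c(1, 0.75), 1)
  # equilibrated starts: exact Gaussian draws at each rung's effective temp
  set.seed(88)
  starts <- lapply(lad$betas, function(b)
    matrix(rnorm(12, sd = sqrt(1 / b)), 4, 3))
  run <- run_grest(hb$system, hb$sel_all, lad, n_sweeps = 60000,
                   exchange_interval = 100, mode = "mc", step_sd = 1.2,
                   seed = 77, start = starts)
  st <- exchange_statistics(run)
  theory <- harmonic_exchange_acceptance(12, 1, 0.75)
  expect_lt(abs(st$pairs$ratio - theory), 3.5 * st$pairs$se)
})
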