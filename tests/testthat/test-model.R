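# Term classification, energy decomposition, scaled potential and forces.

test_that("terms are classified into UU/UV/VV buckets by solute membership", {
  pos <- matrix(rnorm(30), 10, 3)
  sys <- toy_system(pos,
                    charges = rep(c(0.3, -0.3), 5),
                    lj = cbind(epsilon = rep(0.2, 10), sigma = rep(0.9, 10)),
                    dihedrals = data.frame(i = 3, j = 4, k = 5, l = 6,
                                           K = 1, n = 2, delta = 0))
  sel <- solute_selection(c(5, 6), "all")
  cls <- classify_terms(sys, sel)

  dih <- cls[cls$category == "dihedral", ]
  expect_equal(dih$k, 2L)
  expect_equal(dih$l, 4L)
  expect_equal(dih$bucket, "UV")
  expect_equal(dih$exponent, 0.5)

  # LJ pair with neither atom in the solute region
  vd <- cls[cls$category == "vdw", ]
  out_pair <- vd[grepl("vdw", vd$term_id) &
                   apply(sys$pairs[, c("i", "j")], 1,
                         function(r) !any(r %in% c(5, 6))), ][1, ]
  expect_equal(out_pair$k, 0L)
  expect_equal(out_pair$bucket, "VV")

  # elec pair fully inside the solute
  el <- cls[cls$category == "elec", ]
  in_idx <- which(sys$pairs$i == 5 & sys$pairs$j == 6)
  expect_equal(el$k[in_idx], 2L)
  expect_equal(el$bucket[in_idx], "UU")

  expect_error(solute_selection(11, "all", n_atoms = 10), "out of range")
  expect_error(solute_selection(1, character(0)), "non-empty")
})

test_that("unselected categories land in VV regardless of atom membership", {
  sys <- random_system(11)
  sel <- solute_selection(1:3, "dihedral")
  cls <- classify_terms(sys, sel)
  expect_true(all(cls$bucket[cls$category %in% c("vdw", "elec")] == "VV"))
  expect_true(all(cls$bucket[cls$category %in% c("bond", "angle")] == "VV"))
  expect_true(any(cls$bucket[cls$category == "dihedral"] != "VV"))
})

test_that("decomposition buckets sum to the unscaled total energy", {
  for (seed in 1:6) {
    sys <- random_system(seed)
    atoms <- sample(sys$n_atoms, sample(sys$n_atoms, 1))
    cats <- sample(c("dihedral", "vdw", "elec"), sample(3, 1))
    d <- decompose_energy(sys, solute_selection(atoms, cats))
    expect_equal(d$E_uu + sum(d$uv$E) + d$E_vv, d$E_total, tolerance = 1e-12)
    expect_equal(d$E_total, oracle_total_energy(sys), tolerance = 1e-10)
  }
})

test_that("bucket sums match an independent per-term re-summation", {
  ml <- ml_fixture()
  d <- decompose_energy(ml$system, ml$sel, ml$reference)
  ora <- oracle_term_energies(ml$system, ml$reference)
  cls <- classify_terms(ml$system, ml$sel)
  e <- unlist(ora[c("bond", "angle", "dihedral", "restraint", "vdw", "elec")])
  # oracle energies ordered as classify_terms orders its rows
  expect_equal(d$E_uu, sum(e[cls$bucket == "UU"]), tolerance = 1e-9)
  expect_equal(sum(d$uv$E), sum(e[cls$bucket == "UV"]), tolerance = 1e-9)
  expect_equal(d$E_vv, sum(e[cls$bucket == "VV"]), tolerance = 1e-9)
})

test_that("degenerate selections behave as documented", {
  sys <- random_system(3)
  # empty solute: everything is solvent
  d0 <- decompose_energy(sys, solute_selection(integer(), "all"))
  expect_equal(d0$E_uu, 0)
  expect_equal(nrow(d0$uv), 0L)
  expect_equal(d0$E_vv, d0$E_total)

  # single cross pair: 3-atom chain, solute = atom 1, vdw tempered
  sys3 <- toy_system(matrix(c(0, 0, 0, 1.1, 0, 0, 1.9, 0.9, 0), 3, 3,
                            byrow = TRUE),
                     lj = cbind(epsilon = rep(0.3, 3), sigma = rep(1, 3)),
                     bonds = data.frame(i = 1:2, j = 2:3, k = 10, r0 = 1))
  d1 <- decompose_energy(sys3, solute_selection(1, "vdw"))
  expect_equal(d1$E_uu, 0)
  expect_equal(nrow(d1$uv), 1L)  # the (1,3) LJ pair straddles the boundary
  expect_equal(d1$uv$k, 1L)
  expect_equal(d1$uv$l, 2L)
  expect_equal(d1$E_vv, sum(oracle_term_energies(sys3)$bond), tolerance = 1e-10)

  # whole system + all categories: E_vv is bond + angle energy only
  sys6 <- random_system(8)
  dall <- decompose_energy(sys6, solute_selection(1:sys6$n_atoms, "all"))
  ora <- oracle_term_energies(sys6)
  expect_equal(dall$E_vv, sum(ora$bond) + sum(ora$angle), tolerance = 1e-10)

  expect_error(decompose_energy(sys, solute_selection(1, "all"),
                                matrix(NaN, sys$n_atoms, 3)), "non-finite")
})

test_that("scaled potential follows the fractional-exponent form", {
  d <- random_decomposition(1)
  expect_equal(scaled_potential(d, 1, 1), d$E_uu + sum(d$uv$E) + d$E_vv)

  hand <- structure(list(E_uu = 2, uv = data.frame(term_id = "a", E = 1,
                                                   k = 1, l = 2),
                         E_vv = 5), class = "energy_decomposition")
  expect_equal(scaled_potential(hand, 0.25, 1), 6.0)

  # k = l for every cross term collapses to a single factor
  dkl <- random_decomposition(2, kl = c(3, 3))
  s <- 0.37
  expect_equal(scaled_potential(dkl, s, 1),
               s * (dkl$E_uu + sum(dkl$uv$E)) + dkl$E_vv)

  expect_error(scaled_potential(d, -1, 1), "positive")
})

test_that("scaled potential is monotone in beta_m for non-negative buckets", {
  for (seed in 1:5) {
    set.seed(seed)
    d <- structure(list(E_uu = runif(1, 0.1, 3),
                        uv = data.frame(term_id = "a", E = runif(1, 0, 2),
                                        k = 1, l = 2),
                        E_vv = rnorm(1)), class = "energy_decomposition")
    vals <- vapply(seq(0.1, 2, length.out = 15), scaled_potential,
                   numeric(1), decomp = d, beta_0 = 1)
    expect_true(all(diff(vals) >= 0))
  }
})

test_that("scaled forces match central finite differences", {
  ml <- ml_fixture()
  bm <- 0.42; b0 <- 1
  f <- scaled_forces(ml$system, ml$sel, ml$start, bm, b0)
  h <- 1e-6
  err <- 0
  for (i in seq_len(ml$system$n_atoms)) for (q in 1:3) {
    xp <- ml$start; xp[i, q] <- xp[i, q] + h
    xm <- ml$start; xm[i, q] <- xm[i, q] - h
    g <- (scaled_potential(decompose_energy(ml$system, ml$sel, xp), bm, b0) -
          scaled_potential(decompose_energy(ml$system, ml$sel, xm), bm, b0)) / (2 * h)
    err <- max(err, abs(-g - f[i, q]))
  }
  expect_lt(err, 1e-6)
})

test_that("identity scaling reproduces the unscaled force field and empty systems give zero force", {
  sys <- random_system(5)
  sel_none <- solute_selection(integer(), "all")
  sel_some <- solute_selection(2:4, "all")
  f1 <- scaled_forces(sys, sel_some, sys$positions, 1, 1)
  f2 <- scaled_forces(sys, sel_none, sys$positions, 1, 1)
  expect_equal(f1, f2, tolerance = 1e-12)

  lone <- toy_system(matrix(0, 1, 3), nonbonded = FALSE)
  expect_equal(scaled_forces(lone, solute_selection(1, "vdw"),
                             beta_m = 0.5, beta_0 = 1),
               matrix(0, 1, 3))
})
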