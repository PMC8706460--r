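# Independent oracles and shared fixtures for the test suite.  Everything
# here is deliberately written in plain R, independent of the package's
# C++ energy/force path.

# ---- brute-force per-term energy oracle ------------------------------------

.o_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# per-term energies of a toy_system, summed naively in R
oracle_term_energies <- function(system, x = system$positions) {
  out <- list(bond = numeric(0), angle = numeric(0), dihedral = numeric(0),
              restraint = numeric(0), vdw = numeric(0), elec = numeric(0))
  b <- system$bonds
  if (nrow(b)) out$bond <- vapply(seq_len(nrow(b)), function(t) {
    r <- sqrt(sum((x[b$i[t], ] - x[b$j[t], ])^2))
    0.5 * b$k[t] * (r - b$r0[t])^2
  }, numeric(1))
  a <- system$angles
  if (nrow(a)) out$angle <- vapply(seq_len(nrow(a)), function(t) {
    u <- x[a$i[t], ] - x[a$j[t], ]; v <- x[a$k[t], ] - x[a$j[t], ]
    th <- acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
    0.5 * a$kf[t] * (th - a$theta0[t])^2
  }, numeric(1))
  d <- system$dihedrals
  if (nrow(d)) out$dihedral <- vapply(seq_len(nrow(d)), function(t) {
    b1 <- x[d$j[t], ] - x[d$i[t], ]; b2 <- x[d$k[t], ] - x[d$j[t], ]
    b3 <- x[d$l[t], ] - x[d$k[t], ]
    n1 <- .o_cross(b1, b2); n2 <- .o_cross(b2, b3)
    phi <- atan2(sum(.o_cross(n1, n2) * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
    d$K[t] * (1 + cos(d$n[t] * phi - d$delta[t]))
  }, numeric(1))
  r <- system$restraints
  if (nrow(r)) out$restraint <- vapply(seq_len(nrow(r)), function(t) {
    0.5 * r$k[t] * sum((x[r$i[t], ] - c(r$x0[t], r$y0[t], r$z0[t]))^2)
  }, numeric(1))
  p <- system$pairs
  if (nrow(p)) {
    out$vdw <- vapply(seq_len(nrow(p)), function(t) {
      rr <- sqrt(sum((x[p$i[t], ] - x[p$j[t], ])^2))
      4 * p$epsilon[t] * ((p$sigma[t] / rr)^12 - (p$sigma[t] / rr)^6)
    }, numeric(1))
    out$elec <- vapply(seq_len(nrow(p)), function(t) {
      p$qq[t] / sqrt(sum((x[p$i[t], ] - x[p$j[t], ])^2))
    }, numeric(1))
  }
  out
}

oracle_total_energy <- function(system, x = system$positions) {
  sum(unlist(oracle_term_energies(system, x)))
}

# ---- brute-force Kabsch oracle: rotation grid + polish ---------------------

oracle_rmsd <- function(frame, reference, sel = seq_len(nrow(reference))) {
  A <- sweep(frame[sel, , drop = FALSE], 2,
             colMeans(frame[sel, , drop = FALSE]))
  B <- sweep(reference[sel, , drop = FALSE], 2,
             colMeans(reference[sel, , drop = FALSE]))
  rot <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE) %*%
      matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE) %*%
      matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  }
  obj <- function(ang) sqrt(mean(rowSums((A %*% t(rot(ang)) - B)^2)))
  grid <- seq(0, 2 * pi, length.out = 9)[-9]
  best <- c(0, 0, 0); bestv <- obj(best)
  for (a1 in grid) for (a2 in grid) for (a3 in grid) {
    v <- obj(c(a1, a2, a3))
    if (v < bestv) { bestv <- v; best <- c(a1, a2, a3) }
  }
  res <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  res$value
}

# ---- quadrature oracle for harmonic exchange acceptance --------------------

oracle_harmonic_acceptance <- function(f, beta_a, beta_b) {
  a <- f / 2; cc <- beta_b - beta_a
  up <- stats::qgamma(1 - 1e-12, a, rate = min(beta_a, beta_b))
  outer_fn <- function(e1) vapply(e1, function(e1i) {
    inner <- stats::integrate(function(e2)
      pmin(1, exp(-cc * (e1i - e2))) * stats::dgamma(e2, a, rate = beta_b),
      0, up, rel.tol = 1e-9, subdivisions = 400L, stop.on.error = FALSE)$value
    inner * stats::dgamma(e1i, a, rate = beta_a)
  }, numeric(1))
  stats::integrate(outer_fn, 0, up, rel.tol = 1e-8, subdivisions = 400L,
                   stop.on.error = FALSE)$value
}

# ---- random small systems and decompositions -------------------------------

random_system <- function(seed, n = 6) {
  set.seed(seed)
  toy_system(
    positions = matrix(rnorm(3 * n, sd = 1.4), n, 3),
    masses = runif(n, 0.5, 2),
    charges = rnorm(n, 0, 0.4),
    lj = cbind(epsilon = runif(n, 0.05, 0.4), sigma = runif(n, 0.7, 1.1)),
    bonds = data.frame(i = 1:(n - 1), j = 2:n, k = 40, r0 = 1),
    angles = data.frame(i = 1:(n - 2), j = 2:(n - 1), k = 3:n,
                        kf = 6, theta0 = 1.9),
    dihedrals = data.frame(i = 1:(n - 3), j = 2:(n - 2), k = 3:(n - 1),
                           l = 4:n, K = runif(n - 3, 0.5, 2),
                           n = sample(1:3, n - 3, TRUE),
                           delta = runif(n - 3, 0, 2 * pi)))
}

random_decomposition <- function(seed, n_uv = 3, kl = NULL) {
  set.seed(seed)
  kpairs <- if (is.null(kl)) {
    l <- sample(2:4, n_uv, TRUE); k <- vapply(l, function(li) sample(seq_len(li - 1), 1), integer(1))
    cbind(k, l)
  } else matrix(rep(kl, n_uv), ncol = 2, byrow = TRUE)
  structure(list(
    E_uu = rnorm(1, 0, 3),
    uv = data.frame(term_id = paste0("uv.", seq_len(n_uv)),
                    E = rnorm(n_uv, 0, 2),
                    k = kpairs[, 1], l = kpairs[, 2]),
    E_vv = rnorm(1, 0, 3)), class = "energy_decomposition")
}

# ---- shared (memoised) default mini-loop fixture ---------------------------

.fixture_cache <- new.env(parent = emptyenv())

ml_fixture <- function() {
  if (is.null(.fixture_cache$ml)) .fixture_cache$ml <- make_mini_loop()
  .fixture_cache$ml
}
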