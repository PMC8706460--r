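# Synthetic systems and closed-form oracles.  All fixtures are generated in
# code, deterministically from (parameters, seed).

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

#' Harmonic-bath fixture: independent isotropic oscillators
#'
#' `n_solute + n_solvent` beads, each tethered to the origin by a harmonic
#' restraint and otherwise non-interacting (no nonbonded terms), so each
#' bead contributes three independent 1-D harmonic coordinates.  The solute
#' selection covers the first `n_solute` beads with the `"restraint"`
#' category, making the solute energy the only tempered part; choosing all
#' beads as solute instead yields plain T-REMD.  Total energies are
#' Gamma-distributed, so exchange acceptance has a closed form
#' ([harmonic_exchange_acceptance()]).
#'
#' @param n_solute,n_solvent bead counts (>= 1 solute; solvent may be 0).
#' @param k_solute,k_solvent restraint stiffnesses (> 0).
#' @return List with `system` (a [toy_system()]), `sel` (the solute
#'   selection), `sel_all` (whole-system selection, T-REMD), `f_solute` and
#'   `f_solvent` (degrees of freedom, 3 per bead).
#' @export
make_harmonic_bath <- function(n_solute, n_solvent = 0, k_solute = 1,
                               k_solvent = 1) {
  if (n_solute < 1 || n_solvent < 0) stop("bead counts out of range")
  if (k_solute <= 0 || k_solvent <= 0) stop("stiffnesses must be positive")
  n <- n_solute + n_solvent
  pos <- matrix(0, n, 3)
  restraints <- data.frame(i = seq_len(n),
                           k = c(rep(k_solute, n_solute),
                                 rep(k_solvent, n_solvent)),
                           x0 = 0, y0 = 0, z0 = 0)
  system <- toy_system(pos, restraints = restraints, nonbonded = FALSE)
  list(system = system,
       sel = solute_selection(seq_len(n_solute), "restraint"),
       sel_all = solute_selection(seq_len(n), "restraint"),
       f_solute = 3L * n_solute, f_solvent = 3L * n_solvent)
}

#' Closed-form exchange acceptance for harmonic systems
#'
#' For a system of `f` independent harmonic coordinates whose tempered
#' energy is the full energy at each rung, the per-rung energy is
#' Gamma(f/2, beta)-distributed and the mean Metropolis exchange
#' acceptance between rungs at inverse temperatures `beta_a`, `beta_b` has
#' the closed form
#' \deqn{A = 2\,I_{\beta_{\min}/(\beta_a+\beta_b)}(f/2,\, f/2),}
#' with \eqn{I} the regularised incomplete beta function (this follows
#' from the identity \eqn{E[\min(1, e^{-\Delta})] = 2 P(\Delta \le 0)} for
#' equilibrium exchange deltas).  For T-REMD on a bath use the full dof
#' count; for gREST with a solute of `f_u` dof use `f = f_u` — the
#' solvent never enters, which is the E_vv cancellation.
#'
#' @param f degrees of freedom entering the delta.
#' @param beta_a,beta_b inverse temperatures of the two rungs.
#' @return Acceptance probability in (0, 1].
#' @export
harmonic_exchange_acceptance <- function(f, beta_a, beta_b) {
  if (f < 1 || beta_a <= 0 || beta_b <= 0) stop("invalid arguments")
  2 * stats::pbeta(min(beta_a, beta_b) / (beta_a + beta_b), f / 2, f / 2)
}

#' Temperature-ladder spacing achieving a target acceptance
#'
#' Solves for the log-temperature gap \eqn{\ln(T_2/T_1)} between two
#' neighbouring rungs of a harmonic system with `f` degrees of freedom such
#' that the exchange acceptance equals `target`.  The gap shrinks like
#' \eqn{f^{-1/2}}, the quantitative form of the statement that T-REMD
#' exchange probability at fixed spacing decays rapidly with system size.
#'
#' @param f degrees of freedom.
#' @param target desired acceptance in (0, 1).
#' @param beta_a inverse temperature of the lower rung.
#' @return The log-temperature spacing (positive scalar).
#' @export
harmonic_spacing_for_acceptance <- function(f, target = 0.3, beta_a = 1) {
  if (target <= 0 || target >= 1) stop("target must be in (0, 1)")
  g <- function(lt) harmonic_exchange_acceptance(f, beta_a, beta_a / exp(lt)) - target
  stats::uniroot(g, c(1e-8, 50), tol = 1e-12)$root
}

#' Fitted scaling exponent of ladder spacing versus degrees of freedom
#'
#' Computes [harmonic_spacing_for_acceptance()] over a grid of dof counts
#' and returns the least-squares slope of log-spacing against log-f.  The
#' \eqn{f^{-1/2}} law is asymptotic, so the default grid starts at f = 16.
#'
#' @param f_values dof grid.
#' @param target fixed acceptance.
#' @return List with `slope`, `spacings`, `f_values`.
#' @export
ladder_spacing_exponent <- function(f_values = 2^(4:9), target = 0.3) {
  sp <- vapply(f_values, harmonic_spacing_for_acceptance, numeric(1),
               target = target)
  fit <- stats::lm(log(sp) ~ log(f_values))
  list(slope = unname(stats::coef(fit)[2]), spacings = sp, f_values = f_values)
}

#' Bistable mini-loop fixture
#'
#' A bead-chain caricature of a flexible loop grafted on a rigid framework.
#' The framework is a hairpin of two parallel strands (`n_framework` beads,
#' half per strand) tethered to their scaffold positions by stiff
#' restraints; the `n_loop` middle beads bridge the short gap between the
#' strand ends, so the loop carries large slack and must bulge out and pack
#' against itself and the framework, the way a long CDR-type loop protrudes
#' from an immunoglobulin framework.  Loop beads interact through
#' Lennard-Jones spheres and alternating partial charges, and every
#' loop-involving dihedral carries CHARMM-style multi-multiplicity cosine
#' terms whose stiffnesses are graded geometrically from floppy
#' (side-chain-like, K = 0.8) to stiff (omega-bond-like, K = 100): as the
#' tempered categories are scaled down, some dihedral scale softens in
#' every solute-temperature decade, which is what gives an eight-rung
#' ladder exchange susceptibility at every rung.  The central loop dihedral
#' carries a double-well potential \eqn{K(1 - \cos 2\phi)} with wells at
#' \eqn{\phi = 0} (cis) and \eqn{\phi = \pi} (trans) and barrier
#' `barrier` \eqn{= 2K}.  Two minimised structures are emitted: a
#' `reference` in the trans well (the "experimental" structure) and a
#' `start` in the cis well, emulating a start model trapped on the wrong
#' side of the isomerisation barrier.  The solute selection is the loop
#' beads with all tempered categories.
#'
#' @param n_framework framework bead count (>= 2, even split).
#' @param n_loop loop bead count (>= 4).
#' @param barrier double-well barrier height in reduced energy units (> 0).
#' @param seed integer seed for the small symmetry-breaking jitter.
#' @return Object of class `mini_loop`: list with `system` (positions set
#'   to `start`), `sel`, `start`, `reference`, `loop_atoms`,
#'   `framework_atoms`, and `loop_dihedral` (the 4 atoms of the bistable
#'   dihedral).
#' @export
make_mini_loop <- function(n_framework = 12, n_loop = 8, barrier = 8,
                           seed = 1L) {
  if (n_loop < 4) stop("n_loop must be >= 4")
  if (n_framework < 2 || n_framework %% 2 != 0)
    stop("n_framework must be an even count >= 2")
  if (barrier <= 0) stop("barrier height must be positive")
  n <- n_framework + n_loop
  half <- n_framework / 2
  strand_a <- seq_len(half)
  strand_b <- seq(n - half + 1, n)
  framework <- c(strand_a, strand_b)
  loop <- seq(half + 1, n - half)
  theta0 <- 1.911  # tetrahedral-like bond angle

  # hairpin scaffold: strand A out along +x, strand B returning at y = 1.2,
  # both gently zigzagged (collinear triples would make the dihedrals that
  # straddle the framework geometrically degenerate); loop initialised as
  # an arc bulging away from the strands
  scaffold <- matrix(0, n, 3)
  zig <- 0.2 * (-1)^seq_len(half)
  scaffold[strand_a, 1] <- 0.9165 * (seq_len(half) - 1)
  scaffold[strand_a, 2] <- zig
  scaffold[strand_b, 1] <- 0.9165 * rev(seq_len(half) - 1)
  scaffold[strand_b, 2] <- 1.2 + rev(zig)
  p0 <- scaffold[half, ]
  p1 <- scaffold[n - half + 1, ]
  tgrid <- seq(0, pi, length.out = n_loop + 2)[2:(n_loop + 1)]
  radius <- (n_loop + 1) / pi
  centre <- (p0 + p1) / 2
  for (ii in seq_along(loop))
    scaffold[loop[ii], ] <- centre +
      c(sin(tgrid[ii]) * radius * 0.9,
        -cos(tgrid[ii]) * 0.6 * sqrt(sum((p1 - p0)^2)),
        sin(tgrid[ii]) * radius * 0.35)

  bonds <- data.frame(i = 1:(n - 1), j = 2:n, k = 100, r0 = 1)
  tri <- data.frame(i = 1:(n - 2), j = 2:(n - 1), k = 3:n)
  tri <- tri[apply(tri, 1, function(r) any(r %in% loop)), ]
  angles <- data.frame(tri, kf = 6, theta0 = theta0)
  quads <- data.frame(i = 1:(n - 3), j = 2:(n - 2), k = 3:(n - 1), l = 4:n)
  quads <- quads[apply(quads, 1, function(r) any(r %in% loop)), ]
  mid <- loop[ceiling(n_loop / 2) + c(-1, 0, 1, 2)]
  # stiffen the two angles flanking the bistable dihedral (proline-ring-like)
  # so the barrier cannot be bypassed through a collinear chain geometry
  angles$kf[angles$j %in% mid[2:3]] <- 25
  central <- which(quads$i == mid[1])
  # background dihedrals carry CHARMM-style multi-multiplicity terms with
  # geometrically graded stiffnesses (floppy side-chain-like to stiff
  # omega-bond-like): some term then matches every solute-temperature
  # decade, which keeps exchange susceptibility alive across the ladder
  K_grade <- rep(c(0.8, 4, 20, 100), length.out = nrow(quads))
  d1 <- data.frame(quads, K = K_grade, n = 1, delta = 0)
  d3 <- data.frame(quads, K = K_grade / 2, n = 3, delta = 0)
  d1$K[central] <- barrier / 2
  d1$n[central] <- 2
  d1$delta[central] <- pi
  dihedrals <- rbind(d1, d3[-central, ])
  restraints <- data.frame(i = framework, k = 400,
                           x0 = scaffold[framework, 1],
                           y0 = scaffold[framework, 2],
                           z0 = scaffold[framework, 3])
  eps <- rep(1.0, n); eps[loop] <- 1.0

  # structure generation: biased minimisation into each well, retrying with
  # a fresh symmetry-breaking jitter if the minimiser lands in a clashed or
  # wrong-well basin (deterministic given `seed`)
  trans_bias <- data.frame(i = mid[1], j = mid[2], k = mid[3], l = mid[4],
                           K = 50, n = 1, delta = 0)
  cis_bias <- data.frame(i = mid[1], j = mid[2], k = mid[3], l = mid[4],
                         K = 50, n = 1, delta = pi)
  sel_all_atoms <- solute_selection(seq_len(n), "all")
  ok <- FALSE
  diag_msg <- "no attempt run"
  for (attempt in seq_len(20)) {
    jitter <- .with_seed(as.integer(seed) + 7919L * (attempt - 1L),
                         matrix(stats::rnorm(3 * n, sd = 0.02), n, 3))
    build <- function(extra_dihedrals = NULL) {
      toy_system(scaffold + jitter, masses = rep(1, n),
                 charges = 1.8 * (-1)^seq_len(n),
                 lj = cbind(epsilon = eps, sigma = rep(0.9, n)),
                 bonds = bonds, angles = angles,
                 dihedrals = rbind(dihedrals, extra_dihedrals),
                 restraints = restraints)
    }
    system <- build()
    reference <- .minimize(build(trans_bias), sel_all_atoms, scaffold + jitter)
    reference <- .minimize(system, sel_all_atoms, reference)
    cis0 <- .rotate_tail(scaffold + jitter, axis_from = mid[2],
                         axis_to = mid[3], angle = pi)
    start <- .minimize(build(cis_bias), sel_all_atoms, cis0)
    start <- .minimize(system, sel_all_atoms, start)
    phi_start <- measure_dihedral(start, mid)
    phi_ref <- measure_dihedral(reference, mid)
    dmin <- min(min(stats::dist(start)), min(stats::dist(reference)))
    ok <- abs(phi_start) < 1.2 && abs(phi_ref) > 1.9 && dmin > 0.3
    diag_msg <- sprintf("start %.2f, reference %.2f, min distance %.3f",
                        phi_start, phi_ref, dmin)
    if (ok) break
  }
  if (!ok)
    stop("mini-loop generation failed: could not reach separated, clash-free wells (",
         diag_msg, ")")

  system$positions <- start
  structure(list(system = system,
                 sel = solute_selection(loop, "all"),
                 start = start, reference = reference,
                 loop_atoms = loop, framework_atoms = framework,
                 loop_dihedral = mid,
                 barrier = barrier, seed = as.integer(seed)),
            class = "mini_loop")
}

# rotate atoms downstream of axis_to about the (axis_from -> axis_to) axis
.rotate_tail <- function(pos, axis_from, axis_to, angle) {
  ax <- pos[axis_to, ] - pos[axis_from, ]
  ax <- ax / sqrt(sum(ax^2))
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  out <- pos
  tail_idx <- seq(axis_to + 1, nrow(pos))
  origin <- pos[axis_to, ]
  for (i in tail_idx)
    out[i, ] <- origin + as.vector(R %*% (pos[i, ] - origin))
  out
}

#' @export
print.mini_loop <- function(x, ...) {
  cat(sprintf(
    "mini_loop: %d beads (%d loop), barrier %.3g; start dihedral %.2f (cis), reference %.2f (trans)\n",
    x$system$n_atoms, length(x$loop_atoms), x$barrier,
    measure_dihedral(x$start, x$loop_dihedral),
    measure_dihedral(x$reference, x$loop_dihedral)))
  invisible(x)
}
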