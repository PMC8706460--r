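#' Construct a toy molecular system
#'
#' A `toy_system` holds a small bead-model force field in reduced units
#' (k_B = 1, so temperature and energy share a unit and beta = 1/T).  It
#' carries harmonic bonds \eqn{E = k/2 (r - r_0)^2}, harmonic angles
#' \eqn{E = k/2 (\theta - \theta_0)^2}, cosine-series dihedrals
#' \eqn{E = K (1 + \cos(n\phi - \delta))} with the IUPAC sign convention,
#' Lennard-Jones 12-6 plus Coulomb nonbonded pairs (plain, non-periodic, no
#' cutoff; Lorentz-Berthelot combination), and harmonic positional
#' restraints \eqn{E = k/2 |x - x_0|^2}.  1-2 and 1-3 pairs are always
#' excluded from the nonbonded list; 1-4 pairs are included at full
#' strength.
#'
#' @param positions numeric n x 3 matrix of coordinates (reduced length).
#' @param masses numeric vector of length n, all positive.
#' @param charges numeric vector of length n.
#' @param lj two-column matrix or data.frame `(epsilon, sigma)` per atom;
#'   epsilon >= 0, sigma > 0.
#' @param bonds data.frame with columns `i, j, k, r0` (1-based atom indices).
#' @param angles data.frame with columns `i, j, k, kf, theta0` (`j` central).
#' @param dihedrals data.frame with columns `i, j, k, l, K, n, delta`.
#' @param restraints data.frame with columns `i, k, x0, y0, z0`.
#' @param exclusions optional two-column matrix of extra excluded pairs.
#' @param nonbonded logical; if `FALSE` the system has no nonbonded pair
#'   terms at all (used by the independent-oscillator fixtures).
#'
#' @return An object of class `toy_system`.
#' @export
toy_system <- function(positions, masses = NULL, charges = NULL, lj = NULL,
                       bonds = NULL, angles = NULL, dihedrals = NULL,
                       restraints = NULL, exclusions = NULL, nonbonded = TRUE) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L)
    stop("positions must be an n x 3 matrix")
  n <- nrow(positions)
  if (is.null(masses)) masses <- rep(1, n)
  if (is.null(charges)) charges <- rep(0, n)
  if (is.null(lj)) lj <- cbind(epsilon = rep(0, n), sigma = rep(1, n))
  lj <- as.matrix(lj)
  colnames(lj) <- c("epsilon", "sigma")
  stopifnot(length(masses) == n, length(charges) == n, nrow(lj) == n)
  if (any(masses <= 0)) stop("masses must be positive")
  if (any(lj[, "epsilon"] < 0)) stop("epsilon must be non-negative")
  if (any(lj[, "sigma"] <= 0)) stop("sigma must be positive")

  bonds <- .term_table(bonds, c("i", "j", "k", "r0"), n, 2L, "bond")
  angles <- .term_table(angles, c("i", "j", "k", "kf", "theta0"), n, 3L, "angle")
  dihedrals <- .term_table(dihedrals, c("i", "j", "k", "l", "K", "n", "delta"),
                           n, 4L, "dihedral")
  restraints <- .term_table(restraints, c("i", "k", "x0", "y0", "z0"), n, 1L,
                            "restraint")

  excl <- .build_exclusions(bonds, angles, exclusions, n)
  pairs <- if (nonbonded) .build_pairs(n, charges, lj, excl) else
    data.frame(i = integer(), j = integer(), epsilon = numeric(),
               sigma = numeric(), qq = numeric())

  structure(list(
    n_atoms = n, positions = positions, masses = masses, charges = charges,
    lj = lj, bonds = bonds, angles = angles, dihedrals = dihedrals,
    restraints = restraints, exclusions = excl, pairs = pairs,
    nonbonded = nonbonded
  ), class = "toy_system")
}

.term_table <- function(tab, cols, n, n_idx, what) {
  if (is.null(tab) || NROW(tab) == 0) {
    out <- as.data.frame(stats::setNames(rep(list(numeric()), length(cols)), cols))
    return(out)
  }
  tab <- as.data.frame(tab)
  if (ncol(tab) != length(cols))
    stop(sprintf("%s table needs columns %s", what, paste(cols, collapse = ", ")))
  names(tab) <- cols
  idx <- as.matrix(tab[, seq_len(n_idx), drop = FALSE])
  if (any(idx < 1 | idx > n) || any(idx != round(idx)))
    stop(sprintf("%s indices out of range [1, %d]", what, n))
  if (n_idx > 1 && any(apply(idx, 1, function(r) anyDuplicated(r) > 0)))
    stop(sprintf("%s terms must reference distinct atoms", what))
  tab
}

.build_exclusions <- function(bonds, angles, extra, n) {
  ex <- NULL
  if (nrow(bonds) > 0) ex <- rbind(ex, cbind(bonds$i, bonds$j))
  if (nrow(angles) > 0) ex <- rbind(ex, cbind(angles$i, angles$k))
  if (!is.null(extra) && NROW(extra) > 0) {
    extra <- as.matrix(extra)
    if (any(extra < 1 | extra > n)) stop("exclusion indices out of range")
    ex <- rbind(ex, extra)
  }
  if (is.null(ex)) return(matrix(integer(), ncol = 2))
  ex <- t(apply(ex, 1, sort))
  unique(ex)
}

.build_pairs <- function(n, charges, lj, excl) {
  if (n < 2) {
    return(data.frame(i = integer(), j = integer(), epsilon = numeric(),
                      sigma = numeric(), qq = numeric()))
  }
  idx <- utils::combn(n, 2)
  keep <- rep(TRUE, ncol(idx))
  if (nrow(excl) > 0) {
    key <- paste(idx[1, ], idx[2, ])
    exkey <- paste(excl[, 1], excl[, 2])
    keep <- !(key %in% exkey)
  }
  i <- idx[1, keep]; j <- idx[2, keep]
  data.frame(
    i = i, j = j,
    epsilon = sqrt(lj[i, "epsilon"] * lj[j, "epsilon"]),
    sigma = (lj[i, "sigma"] + lj[j, "sigma"]) / 2,
    qq = charges[i] * charges[j]
  )
}

#' @export
print.toy_system <- function(x, ...) {
  cat(sprintf(
    "toy_system: %d atoms | %d bonds, %d angles, %d dihedrals, %d restraints, %d nonbonded pairs\n",
    x$n_atoms, nrow(x$bonds), nrow(x$angles), nrow(x$dihedrals),
    nrow(x$restraints), nrow(x$pairs)))
  invisible(x)
}

#' Designate the tempered "solute" region and term categories
#'
#' In gREST the "solute" is a set of atoms together with the potential-energy
#' term categories that are tempered.  Only dihedral, van der Waals and
#' electrostatic terms are ever scaled in the standard protocol (bond and
#' angle terms stay at the bath temperature); the keyword `"all"` expands to
#' exactly those three.  The additional `"restraint"` category makes
#' single-atom harmonic tethers scalable and exists for the
#' independent-oscillator fixtures, where it is the only energy in the
#' system; it is never part of `"all"`.
#'
#' @param atoms integer vector of solute atom indices (1-based).
#' @param categories character vector drawn from
#'   `c("dihedral", "vdw", "elec", "restraint")`, or the keyword `"all"`
#'   (= dihedral + vdw + elec).
#' @param n_atoms optional atom count for immediate validation.
#'
#' @return An object of class `solute_selection`.
#' @export
solute_selection <- function(atoms, categories = "all", n_atoms = NULL) {
  atoms <- sort(unique(as.integer(atoms)))
  if (length(categories) == 1 && categories == "all")
    categories <- c("dihedral", "vdw", "elec")
  ok <- c("dihedral", "vdw", "elec", "restraint")
  if (length(categories) == 0 || !all(categories %in% ok))
    stop("categories must be non-empty and drawn from: ",
         paste(ok, collapse = ", "), " (or the keyword \"all\")")
  if (!is.null(n_atoms) && length(atoms) > 0 &&
      (min(atoms) < 1 || max(atoms) > n_atoms))
    stop("solute atom indices out of range")
  structure(list(atoms = atoms, categories = unique(categories)),
            class = "solute_selection")
}

#' @export
print.solute_selection <- function(x, ...) {
  cat(sprintf("solute_selection: %d atoms; categories: %s\n",
              length(x$atoms), paste(x$categories, collapse = ", ")))
  invisible(x)
}

.check_selection <- function(system, sel) {
  if (!inherits(sel, "solute_selection")) stop("sel must be a solute_selection")
  if (length(sel$atoms) > 0 &&
      (min(sel$atoms) < 1 || max(sel$atoms) > system$n_atoms))
    stop("solute atom indices out of range for this system")
  invisible(TRUE)
}
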