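#' Classify every potential-energy term against a solute selection
#'
#' Each term is assigned `k` (how many of its atoms lie in the solute
#' region), `l` (its total atom count), and a bucket: `UU` when the term's
#' category is tempered and all atoms are solute (`k = l`), `UV` when the
#' category is tempered and the term straddles the boundary (`0 < k < l`),
#' and `VV` otherwise (including all bond and angle terms, which are never
#' tempered).  A tempered term is scaled by \eqn{(\beta_m/\beta_0)^{k/l}};
#' `VV` terms carry factor 1.
#'
#' @param system a [toy_system()].
#' @param sel a [solute_selection()].
#' @return A data.frame with columns `term_id`, `category`, `k`, `l`,
#'   `bucket`, `exponent`, one row per bonded term and per nonbonded pair
#'   sub-term (each pair contributes one `vdw` and one `elec` row).
#' @export
classify_terms <- function(system, sel) {
  .check_selection(system, sel)
  inside <- function(idx_mat) {
    if (NROW(idx_mat) == 0) return(integer())
    apply(idx_mat, 1, function(r) sum(r %in% sel$atoms))
  }
  rows <- list()
  add <- function(category, idx_mat, l) {
    nt <- NROW(idx_mat)
    if (nt == 0) return()
    k <- inside(idx_mat)
    selected <- category %in% sel$categories
    bucket <- ifelse(!selected | k == 0, "VV", ifelse(k == l, "UU", "UV"))
    expo <- if (selected) k / l else rep(0, nt)
    rows[[length(rows) + 1]] <<- data.frame(
      term_id = paste0(category, ".", seq_len(nt)),
      category = category, k = as.integer(k), l = as.integer(l),
      bucket = bucket, exponent = expo, stringsAsFactors = FALSE)
  }
  add("bond", as.matrix(system$bonds[, c("i", "j")]), 2L)
  add("angle", as.matrix(system$angles[, c("i", "j", "k")]), 3L)
  add("dihedral", as.matrix(system$dihedrals[, c("i", "j", "k", "l")]), 4L)
  add("restraint", as.matrix(system$restraints[, "i", drop = FALSE]), 1L)
  add("vdw", as.matrix(system$pairs[, c("i", "j")]), 2L)
  add("elec", as.matrix(system$pairs[, c("i", "j")]), 2L)
  if (length(rows) == 0)
    return(data.frame(term_id = character(), category = character(),
                      k = integer(), l = integer(), bucket = character(),
                      exponent = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Pack a system + selection into the flat 0-based representation the C++
# kernels consume.  Exponent vectors follow classify_terms().
.pack_system <- function(system, sel) {
  cls <- classify_terms(system, sel)
  expo <- function(category) cls$exponent[cls$category == category]
  m0 <- function(tab, cols) {
    m <- as.matrix(tab[, cols, drop = FALSE])
    if (nrow(m) == 0) return(matrix(numeric(), 0, length(cols)))
    m
  }
  b <- m0(system$bonds, c("i", "j", "k", "r0"))
  a <- m0(system$angles, c("i", "j", "k", "kf", "theta0"))
  d <- m0(system$dihedrals, c("i", "j", "k", "l", "K", "n", "delta"))
  r <- m0(system$restraints, c("i", "k", "x0", "y0", "z0"))
  p <- m0(system$pairs, c("i", "j", "epsilon", "sigma", "qq"))
  if (nrow(b) > 0) b[, 1:2] <- b[, 1:2] - 1
  if (nrow(a) > 0) a[, 1:3] <- a[, 1:3] - 1
  if (nrow(d) > 0) d[, 1:4] <- d[, 1:4] - 1
  if (nrow(r) > 0) r[, 1] <- r[, 1] - 1
  if (nrow(p) > 0) p[, 1:2] <- p[, 1:2] - 1
  list(n_atoms = system$n_atoms, bonds = b, angles = a, dihedrals = d,
       restraints = r, pairs = p,
       eb = expo("bond"), ea = expo("angle"), ed = expo("dihedral"),
       er = expo("restraint"), ev = expo("vdw"), ee = expo("elec"),
       classification = cls)
}

.check_coords <- function(system, x) {
  x <- as.matrix(x)
  if (nrow(x) != system$n_atoms || ncol(x) != 3)
    stop("coordinates must be an n_atoms x 3 matrix")
  if (!all(is.finite(x))) stop("non-finite coordinates")
  x
}

#' Decompose the potential energy into gREST buckets
#'
#' Splits the unscaled potential energy of one configuration into the
#' solute-solute sum `E_uu`, the list of solute-solvent cross terms
#' `E_uv,i` with their exponents `k_i/l_i`, and the solvent-solvent rest
#' `E_vv`.  Terms in unselected categories always land in `E_vv`,
#' regardless of atom membership.  The bucket sums always add up to the
#' unscaled total potential energy.
#'
#' @inheritParams classify_terms
#' @param x coordinates (n x 3); defaults to the system's stored positions.
#' @return An object of class `energy_decomposition`: list with `E_uu`,
#'   `uv` (data.frame `term_id`, `E`, `k`, `l`), `E_vv`, and `E_total`.
#' @export
decompose_energy <- function(system, sel, x = system$positions) {
  x <- .check_coords(system, x)
  packed <- .pack_system(system, sel)
  te <- cpp_term_energies(x, packed)
  cls <- packed$classification
  e <- numeric(nrow(cls))
  for (category in c("bond", "angle", "dihedral", "restraint", "vdw", "elec")) {
    idx <- which(cls$category == category)
    if (length(idx)) e[idx] <- te[[category]]
  }
  uu <- cls$bucket == "UU"; uvb <- cls$bucket == "UV"
  out <- list(
    E_uu = sum(e[uu]),
    uv = data.frame(term_id = cls$term_id[uvb], E = e[uvb],
                    k = cls$k[uvb], l = cls$l[uvb], stringsAsFactors = FALSE),
    E_vv = sum(e[cls$bucket == "VV"]),
    E_total = sum(e))
  class(out) <- "energy_decomposition"
  out
}

#' @export
print.energy_decomposition <- function(x, ...) {
  cat(sprintf("energy_decomposition: E_uu = %.6g, %d uv terms (sum %.6g), E_vv = %.6g, total %.6g\n",
              x$E_uu, nrow(x$uv), sum(x$uv$E), x$E_vv, x$E_total))
  invisible(x)
}

#' Scaled gREST potential energy of a decomposition
#'
#' \deqn{E_m = (\beta_m/\beta_0) E_{uu} +
#'   \sum_i (\beta_m/\beta_0)^{k_i/l_i} E_{uv,i} + E_{vv}.}
#'
#' @param decomp an [decompose_energy()] result.
#' @param beta_m solute inverse temperature (scaling parameter), > 0.
#' @param beta_0 bath inverse temperature, > 0.
#' @return Scaled potential energy (scalar).
#' @export
scaled_potential <- function(decomp, beta_m, beta_0) {
  if (beta_m <= 0 || beta_0 <= 0) stop("inverse temperatures must be positive")
  s <- beta_m / beta_0
  s * decomp$E_uu + sum(s^(decomp$uv$k / decomp$uv$l) * decomp$uv$E) + decomp$E_vv
}

#' Forces under the scaled gREST potential
#'
#' Minus the gradient of [scaled_potential()] with respect to the
#' coordinates; each term's force contribution carries that term's scaling
#' factor \eqn{(\beta_m/\beta_0)^{k/l}}.
#'
#' @inheritParams decompose_energy
#' @param beta_m,beta_0 inverse temperatures, > 0.
#' @return n x 3 matrix of forces.
#' @export
scaled_forces <- function(system, sel, x = system$positions, beta_m, beta_0) {
  if (beta_m <= 0 || beta_0 <= 0) stop("inverse temperatures must be positive")
  x <- .check_coords(system, x)
  packed <- .pack_system(system, sel)
  cpp_scaled_forces(x, packed, beta_m / beta_0)
}

#' Unscaled total potential energy of a configuration
#' @inheritParams decompose_energy
#' @return Scalar potential energy.
#' @export
potential_energy <- function(system, x = system$positions) {
  sel <- solute_selection(integer(), "all")
  decompose_energy(system, sel, x)$E_total
}

# local minimisation under the (optionally scaled) potential
.minimize <- function(system, sel, x, beta_m = 1, beta_0 = 1,
                      maxit = 500) {
  packed <- .pack_system(system, sel)
  s <- beta_m / beta_0
  n <- system$n_atoms
  fn <- function(p) cpp_scaled_energy(matrix(p, n, 3), packed, s)
  gr <- function(p) -as.vector(cpp_scaled_forces(matrix(p, n, 3), packed, s))
  res <- stats::optim(as.vector(x), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit))
  matrix(res$par, n, 3)
}
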