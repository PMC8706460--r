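#' Exactly enumerable discrete system
#'
#' A finite state space where every state carries a fixed energy
#' decomposition (E_uu, cross terms E_uv,i with exponents k_i/l_i, E_vv).
#' The extended-ensemble chain (per-replica Metropolis updates plus
#' parameter exchanges) over such a system can be written down as an exact
#' transition matrix, which is how detailed balance of the sampler is
#' proven rather than estimated.
#'
#' @param E_uu numeric vector: solute-solute energy per state.
#' @param uv optional list of cross terms; each element a list with `E`
#'   (per-state energy vector), `k`, `l`.
#' @param E_vv numeric vector (default 0): solvent-solvent energy per state.
#' @return Object of class `discrete_system`.
#' @export
make_discrete <- function(E_uu, uv = NULL, E_vv = NULL) {
  ns <- length(E_uu)
  if (ns < 2) stop("need at least 2 states")
  if (is.null(E_vv)) E_vv <- rep(0, ns)
  stopifnot(length(E_vv) == ns)
  if (!is.null(uv)) {
    for (term in uv)
      stopifnot(length(term$E) == ns, term$k >= 1, term$k < term$l)
  }
  decomps <- lapply(seq_len(ns), function(x) {
    uvdf <- if (is.null(uv)) {
      data.frame(term_id = character(), E = numeric(), k = integer(),
                 l = integer(), stringsAsFactors = FALSE)
    } else {
      data.frame(term_id = paste0("uv.", seq_along(uv)),
                 E = vapply(uv, function(t) t$E[x], numeric(1)),
                 k = vapply(uv, function(t) t$k, numeric(1)),
                 l = vapply(uv, function(t) t$l, numeric(1)),
                 stringsAsFactors = FALSE)
    }
    structure(list(E_uu = E_uu[x], uv = uvdf, E_vv = E_vv[x],
                   E_total = E_uu[x] + sum(uvdf$E) + E_vv[x]),
              class = "energy_decomposition")
  })
  structure(list(n_states = ns, decomps = decomps), class = "discrete_system")
}

#' Scaled energies of every discrete state at one rung
#' @param dsys a [make_discrete()] system.
#' @param beta_m,beta_0 inverse temperatures.
#' @return Numeric vector over states.
#' @export
discrete_scaled_energies <- function(dsys, beta_m, beta_0) {
  vapply(dsys$decomps, scaled_potential, numeric(1),
         beta_m = beta_m, beta_0 = beta_0)
}

# single-replica Metropolis kernel at rung beta_m: uniform proposal over all
# states (including the current one, for aperiodicity), accept with
# min(1, exp(-beta_0 * dE_scaled))
.discrete_kernel <- function(dsys, beta_m, beta_0) {
  ns <- dsys$n_states
  e <- beta_0 * discrete_scaled_energies(dsys, beta_m, beta_0)
  P <- matrix(0, ns, ns)
  for (x in seq_len(ns)) for (y in seq_len(ns)) {
    if (x == y) next
    P[x, y] <- pmin(1, exp(-(e[y] - e[x]))) / ns
  }
  diag(P) <- 1 - rowSums(P)
  P
}

# all permutations of 1..M (rung index per replica)
.permutations <- function(M) {
  if (M == 1) return(list(1L))
  out <- list()
  for (p in .permutations(M - 1))
    for (pos in seq_len(M))
      out[[length(out) + 1]] <- append(p, M, after = pos - 1)
  lapply(out, as.integer)
}

#' Exact transition matrix of the extended gREST chain on a discrete system
#'
#' Builds the one-cycle transition matrix of the combined chain: one
#' Metropolis update per replica, exchange over the even pair set, another
#' update round, exchange over the odd pair set (mirroring the alternating
#' sweep schedule of [run_grest()]).  Extended states are all combinations
#' of per-replica configurations and rung permutations.
#'
#' @param dsys a [make_discrete()] system.
#' @param ladder a [parameter_ladder()].
#' @return List with `P` (cycle transition matrix), `pi_exact` (the scaled
#'   Boltzmann product law on extended states), `states` (data.frame of
#'   extended-state labels), `stationary` (left Perron eigenvector of `P`),
#'   and `tv` (total-variation distance between the two).
#' @export
discrete_extended_chain <- function(dsys, ladder) {
  ns <- dsys$n_states
  M <- ladder$M
  perms <- .permutations(M)
  configs <- as.matrix(expand.grid(rep(list(seq_len(ns)), M)))  # columns = replicas
  nE <- nrow(configs) * length(perms)
  idx_of <- function(ci, pi_) (pi_ - 1L) * nrow(configs) + ci

  kernels <- lapply(seq_len(M), function(m)
    .discrete_kernel(dsys, ladder$betas[m], ladder$beta_0))

  P_prop <- matrix(0, nE, nE)
  for (pi_ in seq_along(perms)) {
    sigma <- perms[[pi_]]
    for (ci in seq_len(nrow(configs))) for (cj in seq_len(nrow(configs))) {
      p <- 1
      for (a in seq_len(M))
        p <- p * kernels[[sigma[a]]][configs[ci, a], configs[cj, a]]
      P_prop[idx_of(ci, pi_), idx_of(cj, pi_)] <- p
    }
  }

  exch_matrix <- function(pair_set) {
    P <- diag(nE)
    if (length(pair_set) == 0) return(P)
    for (pi_ in seq_along(perms)) {
      sigma <- perms[[pi_]]
      for (ci in seq_len(nrow(configs))) {
        cur <- idx_of(ci, pi_)
        # sequential pairs within one sweep commute here because the pair
        # sets are disjoint in rungs; apply each pair's swap probability
        row <- stats::setNames(1, cur)
        for (m in pair_set) {
          a <- which(sigma == m); b <- which(sigma == m + 1L)
          delta <- exchange_delta(dsys$decomps[[configs[ci, a]]],
                                  dsys$decomps[[configs[ci, b]]],
                                  ladder$betas[m], ladder$betas[m + 1L],
                                  ladder$beta_0)
          p_acc <- exchange_probability(delta)
          new_row <- numeric(0)
          for (j in seq_along(row)) {
            src <- as.integer(names(row)[j])
            pi_src <- (src - 1L) %/% nrow(configs) + 1L
            ci_src <- src - (pi_src - 1L) * nrow(configs)
            sig <- perms[[pi_src]]
            aa <- which(sig == m); bb <- which(sig == m + 1L)
            sig2 <- sig; sig2[aa] <- m + 1L; sig2[bb] <- m
            pi_dst <- which(vapply(perms, function(pp) all(pp == sig2), logical(1)))
            dst <- idx_of(ci_src, pi_dst)
            new_row[as.character(dst)] <-
              (if (is.na(new_row[as.character(dst)])) 0 else
                new_row[as.character(dst)]) + row[j] * p_acc
            new_row[as.character(src)] <-
              (if (is.na(new_row[as.character(src)])) 0 else
                new_row[as.character(src)]) + row[j] * (1 - p_acc)
          }
          row <- new_row[!is.na(new_row)]
        }
        P[cur, ] <- 0
        P[cur, as.integer(names(row))] <- row
      }
    }
    P
  }

  even <- as.integer(seq(1, M - 1, by = 2))
  odd <- if (M > 2) as.integer(seq(2, M - 1, by = 2)) else integer()
  P <- P_prop %*% exch_matrix(even) %*% P_prop %*% exch_matrix(odd)

  # exact product law: pi(x_1..x_M, sigma) ~ prod_a exp(-beta0 * E_sigma(a)(x_a))
  log_w <- matrix(0, ns, M)
  for (m in seq_len(M))
    log_w[, m] <- -ladder$beta_0 *
      discrete_scaled_energies(dsys, ladder$betas[m], ladder$beta_0)
  pi_exact <- numeric(nE)
  for (pi_ in seq_along(perms)) {
    sigma <- perms[[pi_]]
    for (ci in seq_len(nrow(configs))) {
      lw <- 0
      for (a in seq_len(M)) lw <- lw + log_w[configs[ci, a], sigma[a]]
      pi_exact[idx_of(ci, pi_)] <- exp(lw)
    }
  }
  pi_exact <- pi_exact / sum(pi_exact)

  ev <- eigen(t(P))
  i1 <- which.min(abs(ev$values - 1))
  stat <- Re(ev$vectors[, i1])
  stat <- stat / sum(stat)

  states <- data.frame(
    config = rep(apply(configs, 1, paste, collapse = ","), length(perms)),
    perm = rep(vapply(perms, paste, character(1), collapse = ","),
               each = nrow(configs)))
  list(P = P, pi_exact = pi_exact, stationary = stat, states = states,
       tv = 0.5 * sum(abs(stat - pi_exact)))
}

#' Simulate the discrete extended chain
#'
#' Runs the same chain as [discrete_extended_chain()] describes, by direct
#' simulation, and returns the empirical occupancy of the per-rung
#' configuration tuple (x at rung 1, ..., x at rung M).
#'
#' @param dsys a [make_discrete()] system.
#' @param ladder a [parameter_ladder()].
#' @param n_steps Metropolis update rounds.
#' @param exchange_interval rounds between exchange sweeps (1 = every round).
#' @param seed integer seed.
#' @return List with `freq` (named empirical probabilities) and
#'   `exact` (the product-law probabilities of the same tuples).
#' @export
simulate_discrete_grest <- function(dsys, ladder, n_steps = 1e5,
                                    exchange_interval = 1, seed = 1L) {
  ns <- dsys$n_states
  M <- ladder$M
  emat <- vapply(seq_len(M), function(m)
    ladder$beta_0 * discrete_scaled_energies(dsys, ladder$betas[m], ladder$beta_0),
    numeric(ns))
  ddelta <- numeric((M - 1) * ns * ns)
  if (M > 1) {
    for (m in seq_len(M - 1)) for (xa in seq_len(ns)) for (xb in seq_len(ns))
      ddelta[(m - 1) * ns * ns + (xa - 1) * ns + xb - 1 + 1] <-
        exchange_delta(dsys$decomps[[xa]], dsys$decomps[[xb]],
                       ladder$betas[m], ladder$betas[m + 1], ladder$beta_0)
  }
  res <- cpp_discrete_run(emat, ddelta, M, as.integer(n_steps),
                          as.integer(exchange_interval),
                          as.integer(c(seed, 97)))
  counts <- res$counts
  # key enumeration in C++: key = x_rung1 * ns^(M-1) + ... + x_rungM (0-based)
  tuples <- as.matrix(expand.grid(rep(list(0:(ns - 1L)), M)))  # col m = rung m
  keys <- as.vector(tuples %*% ns^(M - seq_len(M)))
  freq <- counts[keys + 1] / sum(counts)
  log_w <- vapply(seq_len(M), function(m)
    -ladder$beta_0 * discrete_scaled_energies(dsys, ladder$betas[m], ladder$beta_0),
    numeric(ns))
  exact <- apply(tuples + 1L, 1, function(r)
    exp(sum(log_w[cbind(r, seq_len(M))])))
  exact <- exact / sum(exact)
  nm <- apply(tuples + 1L, 1, paste, collapse = ",")
  list(freq = stats::setNames(freq, nm), exact = stats::setNames(exact, nm))
}
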