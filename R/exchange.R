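#' gREST exchange delta between two replicas
#'
#' The detailed-balance exponent for swapping scaling parameters
#' \eqn{\beta_m} (held by replica a) and \eqn{\beta_n} (replica b):
#' \deqn{\Delta = (\beta_n - \beta_m)\,(E_{uu}(x_a) - E_{uu}(x_b)) +
#'   \sum_i \beta_0^{1 - k_i/l_i}\,(\beta_n^{k_i/l_i} - \beta_m^{k_i/l_i})
#'   \,(E_{uv,i}(x_a) - E_{uv,i}(x_b)).}
#' The swap is accepted with probability \eqn{\min(1, e^{-\Delta})}.  When
#' every cross term has \eqn{k_i = l_i/2} this is the REST2 delta; when the
#' whole system (all categories) is the solute it is the T-REMD delta and
#' the solvent-solvent energy has cancelled out entirely.
#'
#' @param decomp_a,decomp_b [decompose_energy()] results for the two
#'   replicas, produced under the same solute selection.
#' @param beta_m,beta_n the two scaling parameters.
#' @param beta_0 bath inverse temperature.
#' @return The scalar delta.
#' @export
exchange_delta <- function(decomp_a, decomp_b, beta_m, beta_n, beta_0) {
  if (nrow(decomp_a$uv) != nrow(decomp_b$uv) ||
      !identical(decomp_a$uv$term_id, decomp_b$uv$term_id))
    stop("uv term lists of the two decompositions are not aligned")
  d <- (beta_n - beta_m) * (decomp_a$E_uu - decomp_b$E_uu)
  if (nrow(decomp_a$uv) > 0) {
    kl <- decomp_a$uv$k / decomp_a$uv$l
    d <- d + sum(beta_0^(1 - kl) * (beta_n^kl - beta_m^kl) *
                   (decomp_a$uv$E - decomp_b$uv$E))
  }
  d
}

#' Metropolis exchange-acceptance probability
#'
#' \eqn{P = 1} for \eqn{\Delta \le 0}, \eqn{e^{-\Delta}} otherwise.
#'
#' @param delta exchange delta.
#' @return Acceptance probability in (0, 1].
#' @export
exchange_probability <- function(delta) {
  ifelse(delta <= 0, 1, exp(-delta))
}

#' Metropolis accept/reject decision
#'
#' Accepts deterministically when `delta <= 0` (consuming no random draw);
#' otherwise consumes exactly one uniform draw `u` from the current R RNG
#' stream and accepts iff `u <= exp(-delta)`.
#'
#' @param delta exchange delta.
#' @return Logical.
#' @export
metropolis_accept <- function(delta) {
  if (delta <= 0) return(TRUE)
  stats::runif(1) <= exp(-delta)
}
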