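#' Parameter ladder of solute inverse temperatures
#'
#' The ordered scaling parameters \eqn{\beta_1 > \beta_2 > \dots > \beta_M}
#' (equivalently solute "temperatures" \eqn{T_m = 1/\beta_m} in reduced
#' units, k_B = 1).  The first rung is pinned to the bath:
#' \eqn{\beta_1 = \beta_0}, so the rung-1 trajectory samples the unscaled
#' ensemble.
#'
#' @param betas strictly decreasing vector of positive inverse temperatures.
#' @param beta_0 bath inverse temperature; must equal `betas[1]`.
#' @return Object of class `parameter_ladder`.
#' @export
parameter_ladder <- function(betas, beta_0 = betas[1]) {
  betas <- as.numeric(betas)
  if (length(betas) < 1 || any(betas <= 0)) stop("betas must be positive")
  if (any(diff(betas) >= 0)) stop("betas must be strictly decreasing")
  if (abs(betas[1] - beta_0) > 1e-12)
    stop("beta_1 must equal the bath inverse temperature beta_0")
  structure(list(betas = betas, beta_0 = beta_0, M = length(betas)),
            class = "parameter_ladder")
}

#' Geometric initial ladder in solute temperature
#'
#' Rungs are geometrically spaced in solute temperature between the bath
#' temperature `T0` and `T_max` (default 5 * T0), the standard starting
#' point before acceptance-targeted optimization.
#'
#' @param M number of replicas (>= 1).
#' @param T0 bath temperature (reduced units).
#' @param T_max solute temperature of the top rung.
#' @return A [parameter_ladder()].
#' @export
geometric_ladder <- function(M, T0 = 1, T_max = 5 * T0) {
  if (M < 1) stop("M must be >= 1")
  if (M == 1) return(parameter_ladder(1 / T0, 1 / T0))
  Tm <- T0 * (T_max / T0)^((seq_len(M) - 1) / (M - 1))
  parameter_ladder(1 / Tm, 1 / T0)
}

#' @export
print.parameter_ladder <- function(x, ...) {
  cat(sprintf("parameter_ladder: M = %d, T = %s\n", x$M,
              paste(signif(1 / x$betas, 4), collapse = ", ")))
  invisible(x)
}
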