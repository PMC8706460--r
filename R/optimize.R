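#' Optimize the parameter ladder toward a target exchange acceptance
#'
#' Starting from a ladder geometric in solute temperature, runs short gREST
#' trials, measures the per-pair neighbour acceptance p_m, and updates the
#' log-temperature gaps multiplicatively,
#' \deqn{\ln(T_{m+1}/T_m) \leftarrow \ln(T_{m+1}/T_m) \cdot
#'   \frac{\ln p^\ast}{\ln \max(p_m, \epsilon)},}
#' until every pair sits within `tolerance` of the target \eqn{p^\ast}
#' (default 0.3, the standard production target) or `max_rounds` is
#' reached.  The bottom rung \eqn{\beta_1 = \beta_0} is never modified.
#' The measured acceptance is a noisy binomial estimate, so per-round
#' update factors are clamped to [0.5, 2] and p_m to [0.02, 0.95] for
#' stability.  Trial runs re-use the final coordinates of the previous
#' round as their start, so later rounds measure acceptance on
#' progressively better-equilibrated replicas.
#'
#' @inheritParams run_grest
#' @param M number of replicas (>= 2).
#' @param target target neighbour acceptance, in (0, 1).
#' @param tolerance convergence band around the target.
#' @param max_rounds maximum optimization rounds.
#' @param T_max top solute temperature of the initial geometric ladder.
#' @param trial_sweeps sampler steps per replica per trial round.
#' @param trial_exchange_interval exchange interval during trials (shorter
#'   than production to gather acceptance statistics quickly).
#' @param ladder optional starting [parameter_ladder()]; when `NULL` a
#'   geometric ladder between `T0 = 1` and `T_max` is used.
#' @return A [parameter_ladder()] with attributes `converged` (logical),
#'   `acceptance` (per-pair acceptance of the last trial), and `history`
#'   (per-round per-pair acceptance matrix).  Warns on non-convergence.
#' @export
optimize_ladder <- function(system, sel, M, target = 0.3, tolerance = 0.05,
                            max_rounds = 15, seed = 1L, T_max = NULL,
                            trial_sweeps = 32000,
                            trial_exchange_interval = 160,
                            mode = c("mc", "langevin"), dt = 0.01,
                            friction = 2, step_sd = 0.12, start = NULL,
                            ladder = NULL) {
  mode <- match.arg(mode)
  if (M < 2) stop("ladder optimization needs M >= 2")
  if (target <= 0 || target >= 1) stop("target acceptance must be in (0, 1)")
  if (is.null(ladder)) {
    T0 <- 1
    if (is.null(T_max)) T_max <- 5 * T0
    ladder <- geometric_ladder(M, T0, T_max)
  } else {
    if (ladder$M != M) stop("supplied ladder does not have M rungs")
    T0 <- 1 / ladder$beta_0
  }
  history <- NULL
  acc <- rep(NA_real_, M - 1)
  converged <- FALSE
  for (round in seq_len(max_rounds)) {
    trial <- run_grest(system, sel, ladder, n_sweeps = trial_sweeps,
                       exchange_interval = trial_exchange_interval,
                       seed = as.integer(seed) + round, mode = mode, dt = dt,
                       friction = friction, step_sd = step_sd, start = start)
    start <- .final_coords(trial)
    acc <- .pair_acceptance(trial$exchange_log, M)
    history <- rbind(history, acc)
    if (all(abs(acc - target) <= tolerance)) { converged <- TRUE; break }
    p <- pmin(pmax(acc, 0.02), 0.95)
    factor <- pmin(pmax(log(target) / log(p), 0.5), 2)
    gaps <- diff(log(1 / ladder$betas)) * factor
    Tm <- exp(pmin(cumsum(c(log(T0), gaps)), log(1e6 * T0)))
    Tm <- Tm * (1 + 1e-9 * (seq_len(M) - 1))  # keep rungs distinct at the cap
    ladder <- parameter_ladder(1 / Tm, 1 / T0)
  }
  if (!converged)
    warning(sprintf(
      "ladder optimization did not converge in %d rounds (worst deviation %.3f)",
      max_rounds, max(abs(acc - target))))
  attr(ladder, "converged") <- converged
  attr(ladder, "acceptance") <- acc
  attr(ladder, "history") <- unname(history)
  ladder
}

.pair_acceptance <- function(log, M) {
  vapply(seq_len(M - 1), function(m) {
    rows <- log$pair == m
    if (!any(rows)) return(NA_real_)
    mean(log$accepted[rows])
  }, numeric(1))
}

.final_coords <- function(run) {
  M <- run$config$M
  lapply(seq_len(M), function(a) {
    idx <- which(run$frames$replica == a)
    run$frames$coords[[idx[length(idx)]]]
  })
}
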