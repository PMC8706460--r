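#' Run a gREST simulation
#'
#' Alternates propagation blocks of `exchange_interval` sampler steps with
#' neighbour exchange sweeps.  All replicas run at the common bath
#' temperature `1/beta_0`; only the scaling parameter beta_m of the solute
#' terms differs between rungs.  Exchange phases alternate between the even
#' pair set (1,2), (3,4), ... and the odd set (2,3), (4,5), ...; within a
#' phase pairs are evaluated in ascending rung order.  On acceptance the
#' two replicas swap parameter indices (coordinates and velocities stay
#' with their replicas).  The run is fully reproducible from `seed`: R's
#' RNG (seeded once) drives velocity initialisation and exchange decisions,
#' while each propagation chunk uses its own counter-based stream derived
#' from `(seed, replica, chunk)`.
#'
#' @inheritParams propagate
#' @param ladder a [parameter_ladder()]; `ladder$M` replicas are run.
#' @param n_sweeps total sampler steps per replica; must be a multiple of
#'   `exchange_interval`.
#' @param exchange_interval steps between exchange attempts (default 1000).
#' @param record_interval steps between recorded frames; must divide
#'   `exchange_interval`.
#' @param start starting coordinates: a single n x 3 matrix used for every
#'   replica, or a list of M matrices.  Defaults to the system's positions.
#' @param seed single integer controlling all randomness of the run.
#' @return Object of class `grest_run`: list with `frames` (coordinates and
#'   per-frame energy decompositions), `exchange_log`, `mapping_history`
#'   (per exchange phase, rung index of each replica), `ladder`, `sel`,
#'   and the resolved `config`.
#' @export
run_grest <- function(system, sel, ladder, n_sweeps,
                      exchange_interval = 1000, seed = 1L,
                      mode = c("mc", "langevin"), dt = 0.01, friction = 2,
                      step_sd = 0.12, start = NULL,
                      record_interval = exchange_interval) {
  mode <- match.arg(mode)
  if (!inherits(ladder, "parameter_ladder")) stop("ladder must be a parameter_ladder")
  M <- ladder$M
  if (M < 1) stop("ladder must have at least one rung")
  .check_selection(system, sel)
  if (n_sweeps %% exchange_interval != 0)
    stop("n_sweeps must be a multiple of exchange_interval")
  if (exchange_interval %% record_interval != 0)
    stop("record_interval must divide exchange_interval")
  n_blocks <- n_sweeps %/% exchange_interval
  chunks_per_block <- exchange_interval %/% record_interval

  if (is.null(start)) start <- system$positions
  xs <- if (is.list(start)) start else rep(list(.check_coords(system, start)), M)
  if (length(xs) != M) stop("start must supply one structure or M structures")

  set.seed(as.integer(seed))
  vs <- if (mode == "langevin")
    lapply(seq_len(M), function(a) .maxwell_boltzmann(system$masses, 1 / ladder$beta_0))
  else vector("list", M)

  packed <- .pack_system(system, sel)
  n_uv <- sum(packed$classification$bucket == "UV")
  m_of_a <- seq_len(M)

  n_frames <- n_blocks * chunks_per_block * M
  fr_coords <- vector("list", n_frames)
  fr_sweep <- integer(n_frames); fr_replica <- integer(n_frames)
  fr_param <- integer(n_frames)
  fr_Euu <- numeric(n_frames); fr_Evv <- numeric(n_frames)
  fr_Euv <- matrix(0, n_frames, n_uv)
  fr_Escaled <- numeric(n_frames)

  log_phase <- integer(); log_sweep <- integer(); log_pair <- integer()
  log_a <- integer(); log_b <- integer(); log_delta <- numeric()
  log_acc <- logical()
  mapping_history <- matrix(NA_integer_, n_blocks + 1, M)
  mapping_history[1, ] <- m_of_a

  decomp_of <- function(x) {
    te <- cpp_term_energies(x, packed)
    cls <- packed$classification
    e <- numeric(nrow(cls))
    for (category in c("bond", "angle", "dihedral", "restraint", "vdw", "elec")) {
      idx <- which(cls$category == category)
      if (length(idx)) e[idx] <- te[[category]]
    }
    uvb <- cls$bucket == "UV"
    list(E_uu = sum(e[cls$bucket == "UU"]), E_uv = e[uvb],
         E_vv = sum(e[cls$bucket == "VV"]),
         uv = data.frame(term_id = cls$term_id[uvb], E = e[uvb],
                         k = cls$k[uvb], l = cls$l[uvb]))
  }

  chunk_id <- 0L
  fi <- 0L
  decomps <- vector("list", M)
  for (blk in seq_len(n_blocks)) {
    for (a in seq_len(M)) {
      s <- ladder$betas[m_of_a[a]] / ladder$beta_0
      for (ch in seq_len(chunks_per_block)) {
        chunk_seed <- c(as.integer(seed), a, chunk_id + ch)
        if (mode == "mc") {
          res <- cpp_mc_run(xs[[a]], packed, s, ladder$beta_0,
                            record_interval, step_sd, chunk_seed)
          xs[[a]] <- res$pos
        } else {
          res <- cpp_langevin_run(xs[[a]], vs[[a]], system$masses, packed, s,
                                  ladder$beta_0, record_interval, dt,
                                  friction, chunk_seed)
          xs[[a]] <- res$pos; vs[[a]] <- res$vel
        }
        d <- decomp_of(xs[[a]])
        fi <- fi + 1L
        fr_coords[[fi]] <- xs[[a]]
        fr_sweep[fi] <- (blk - 1L) * exchange_interval + ch * record_interval
        fr_replica[fi] <- a
        fr_param[fi] <- m_of_a[a]
        fr_Euu[fi] <- d$E_uu; fr_Evv[fi] <- d$E_vv
        if (n_uv > 0) fr_Euv[fi, ] <- d$E_uv
        sm <- ladder$betas[m_of_a[a]] / ladder$beta_0
        fr_Escaled[fi] <- sm * d$E_uu +
          sum(sm^(d$uv$k / d$uv$l) * d$E_uv) + d$E_vv
        if (ch == chunks_per_block) decomps[[a]] <- d
      }
    }
    chunk_id <- chunk_id + chunks_per_block

    if (M > 1) {
      a_of_m <- order(m_of_a)
      first <- if (blk %% 2L == 1L) 1L else 2L
      for (m in if (first > M - 1L) integer() else seq(first, M - 1L, by = 2L)) {
        a <- a_of_m[m]; b <- a_of_m[m + 1L]
        da <- decomps[[a]]; db <- decomps[[b]]
        dl <- exchange_delta(
          structure(list(E_uu = da$E_uu, uv = da$uv, E_vv = da$E_vv),
                    class = "energy_decomposition"),
          structure(list(E_uu = db$E_uu, uv = db$uv, E_vv = db$E_vv),
                    class = "energy_decomposition"),
          ladder$betas[m], ladder$betas[m + 1L], ladder$beta_0)
        acc <- metropolis_accept(dl)
        log_phase <- c(log_phase, blk)
        log_sweep <- c(log_sweep, blk * exchange_interval)
        log_pair <- c(log_pair, m)
        log_a <- c(log_a, a); log_b <- c(log_b, b)
        log_delta <- c(log_delta, dl); log_acc <- c(log_acc, acc)
        if (acc) {
          m_of_a[a] <- m + 1L; m_of_a[b] <- m
          a_of_m[m] <- b; a_of_m[m + 1L] <- a
        }
      }
    }
    mapping_history[blk + 1L, ] <- m_of_a
  }

  structure(list(
    frames = list(coords = fr_coords, sweep = fr_sweep, replica = fr_replica,
                  param = fr_param, E_uu = fr_Euu, E_vv = fr_Evv,
                  E_uv = fr_Euv, E_scaled = fr_Escaled),
    exchange_log = data.frame(phase = log_phase, sweep = log_sweep,
                              pair = log_pair, replica_a = log_a,
                              replica_b = log_b, delta = log_delta,
                              accepted = log_acc),
    mapping_history = mapping_history,
    ladder = ladder, sel = sel,
    config = list(n_sweeps = n_sweeps, exchange_interval = exchange_interval,
                  record_interval = record_interval, seed = seed, mode = mode,
                  dt = dt, friction = friction, step_sd = step_sd, M = M)
  ), class = "grest_run")
}

#' @export
print.grest_run <- function(x, ...) {
  nacc <- sum(x$exchange_log$accepted)
  natt <- nrow(x$exchange_log)
  cat(sprintf(
    "grest_run: M = %d, %d sweeps (%s), %d frames, %d/%d exchanges accepted (%.3f)\n",
    x$config$M, x$config$n_sweeps, x$config$mode, length(x$frames$coords),
    nacc, natt, if (natt > 0) nacc / natt else NA))
  invisible(x)
}
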