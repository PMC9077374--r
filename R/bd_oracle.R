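# Brownian-dynamics reference simulator for tiny systems: the independent
# validation oracle for the IRT engine. Production runs never use it.

#' Brownian-dynamics parameters
#'
#' The timestep rule `sqrt(2 * D_max * dt) < R_min / 5` keeps the r.m.s.
#' per-step displacement well below the smallest encounter radius so that
#' end-of-step encounter detection (no bridging correction) is accurate.
#'
#' @param dt timestep, ps.
#' @param t_end end of the simulated window, ps.
#' @param n_rep number of independent replicates.
#' @return A `bd_params` list.
#' @export
bd_params <- function(dt, t_end, n_rep = 2000L) {
  stopifnot(dt > 0, t_end > dt, n_rep >= 1)
  structure(list(dt = dt, t_end = t_end, n_rep = as.integer(n_rep)),
            class = "bd_params")
}

check_bd_step <- function(dt, D_max, R_min) {
  if (sqrt(2 * D_max * dt) >= R_min / 5) {
    stop(sprintf(paste0("BD timestep too coarse: sqrt(2 D dt) = %.3g nm ",
                        "must be < R/5 = %.3g nm"),
                 sqrt(2 * D_max * dt), R_min / 5))
  }
  invisible(TRUE)
}

#' Pair survival probability by Brownian dynamics
#'
#' Propagates the inter-particle separation of an isolated pair as 3-D
#' Gaussian displacements with the mutual diffusion coefficient and records
#' the first passage below the encounter radius. With `q = Inf` (default)
#' the encounter surface is perfectly absorbing (fully diffusion-controlled
#' limit); a finite `q` (ps^-1) applies the volume-reactivity rule -- react
#' with probability 1 - exp(-q dt) per step spent inside R -- whose
#' long-time rate is \eqn{4\pi D R N_A (1 - \tanh x / x)} with
#' \eqn{x = R\sqrt{q/D}} (see [bd_tune_q()]).
#'
#' @param r0 initial separation, nm (> R).
#' @param R encounter radius, nm (R = 0 means no sink).
#' @param D mutual diffusion coefficient, nm^2/ps.
#' @param times monitoring times, ps (the last one ends the run).
#' @param params a [bd_params()]; its `t_end` is ignored in favour of
#'   `max(times)`.
#' @param q volume reactivity inside R, ps^-1 (`Inf` = absorbing).
#' @return data.frame `time`, `S` (survival fraction), `se` (binomial).
#' @export
bd_pair_survival <- function(r0, R, D, times, params, q = Inf) {
  stopifnot(r0 > R, D > 0, all(diff(times) > 0))
  if (R > 0) check_bd_step(params$dt, D, R)
  reacted <- .bd_pair_cpp(r0, R, D, params$dt, times, params$n_rep, q)
  S <- 1 - reacted / params$n_rep
  data.frame(time = times, S = S,
             se = sqrt(pmax(S * (1 - S), 1 / params$n_rep^2) / params$n_rep))
}

#' Tune the volume reactivity to a target observed rate constant
#'
#' Inverts the Doi (volume-reactivity) steady-state rate
#' \eqn{k_{obs} = k_{diff} (1 - \tanh x / x)}, \eqn{x = R\sqrt{q/D}}, for
#' the per-step reaction rate `q` that makes the Brownian-dynamics partial
#' reactivity model reproduce a Collins-Kimball observed rate constant.
#'
#' @param k_obs target observed rate constant, M^-1 s^-1.
#' @param R encounter radius, nm.
#' @param D mutual diffusion coefficient, nm^2/ps.
#' @return q in ps^-1.
#' @export
bd_tune_q <- function(k_obs, R, D) {
  k_diff <- 4 * pi * D * R / K_M1S1_TO_NM3PS
  ratio <- k_obs / k_diff
  if (ratio >= 1) stop("k_obs must be below the diffusion limit 4*pi*N_A*D*R")
  f <- function(x) 1 - tanh(x) / x - ratio
  x <- stats::uniroot(f, c(1e-8, 1e6), tol = 1e-12)$root
  D * (x / R)^2
}

#' Brownian-dynamics simulation of a small reactive cluster
#'
#' Full random-flight propagation of every particle of a small (<= 10
#' particles) initial configuration with all pairwise encounter tests per
#' step and pseudo-first-order channels on exponential clocks. Reaction
#' products are treated as chemically inert (the oracle is meant for
#' fixture networks whose products do not react further). Returns the
#' cumulative reacted fraction per channel for comparison with
#' [run_history()] ensembles.
#'
#' @param config a `track_config`-like list (`particles`, `energy`).
#' @param compiled a [compile_engine()] result for the fixture network.
#' @param times monitoring times, ps (measured from the 1-ps start).
#' @param params a [bd_params()].
#' @return data.frame `time`, `channel`, `events` (mean per replicate),
#'   `se`.
#' @export
bd_cluster <- function(config, compiled, times, params) {
  parts <- config$particles
  stopifnot(nrow(parts) <= 10, all(diff(times) > 0))
  sp <- match(parts$species, compiled$track) - 1L
  if (anyNA(sp)) stop("unknown track species in fixture")
  if (length(compiled$pair$R)) {
    Dm <- max(compiled$D_track[c(compiled$pair$a, compiled$pair$b) + 1L])
    check_bd_step(params$dt, 2 * Dm, min(compiled$pair$R))
  }
  nrx <- length(compiled$rxn_ids)
  counts <- .bd_cluster_cpp(
    as.matrix(parts[, c("x", "y", "z")]), as.integer(sp),
    compiled$D_track,
    compiled$pair$a, compiled$pair$b, compiled$pair$R, compiled$pair$rid,
    rep(Inf, length(compiled$pair$R)),
    compiled$fo$spec, compiled$fo$rate, compiled$fo$rid,
    nrx, params$dt, times, params$n_rep)
  frac <- counts / params$n_rep
  data.frame(time = rep(times, each = nrx),
             channel = rep(compiled$rxn_ids, length(times)),
             events = as.vector(frac),
             se = as.vector(sqrt(pmax(frac, 1e-12) / params$n_rep)))
}
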