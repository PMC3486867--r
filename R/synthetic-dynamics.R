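#' Kinetic parameters of the coarse-grained constant-pH simulator
#'
#' The simulator is a discrete-time Markov chain, one frame per step, with
#' two move types: a Metropolis protonation flip attempted periodically
#' (every `mc_interval` steps, mirroring the periodic Monte Carlo
#' protonation sampling interleaved with molecular dynamics in constant-pH
#' MD), and a Metropolis conformational flip attempted with a small
#' per-step probability so that conformational motion is roughly two
#' orders of magnitude slower than protonation exchange — the regime in
#' which deprotonation visibly precedes opening. Rates are fictitious;
#' only the stationary (equilibrium) statistics are physical.
#'
#' @param n_steps Number of chain steps (= recorded frames).
#' @param mc_interval Steps between protonation attempts (default 10).
#' @param p_conf_attempt Per-step probability of attempting a
#'   conformational flip, in (0, 1] (default 0.01); 0 freezes the
#'   conformation.
#' @param seed Integer RNG seed.
#' @param burn_in Fraction of initial frames treated as equilibration by
#'   downstream estimators (default 0.1).
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(n_steps = 1e5, mc_interval = 10L,
                           p_conf_attempt = 0.01, seed = 1L,
                           burn_in = 0.1) {
  n_steps <- as.integer(n_steps)
  mc_interval <- as.integer(mc_interval)
  stopifnot(n_steps > 0L, mc_interval >= 1L,
            p_conf_attempt >= 0, p_conf_attempt <= 1,
            burn_in >= 0, burn_in < 1)
  structure(list(n_steps = n_steps, mc_interval = mc_interval,
                 p_conf_attempt = p_conf_attempt,
                 seed = as.integer(seed), burn_in = burn_in),
            class = "kinetic_params")
}

#' Conformation-conditioned observable emission model
#'
#' Gaussian emission parameters per conformation for the three monitored
#' observables: the Asp30-Leu130 hydrogen-bond distance, the
#' Asp35-Asp129 escape-route distance (both in Angstrom) and the
#' solvent-accessible surface area of the titratable carboxylate (in
#' square Angstrom, truncated at zero by resampling). Defaults are the
#' stable-simulation summary values for the closed (pH 5.5) and open
#' (pH 7.5) states of nitrophorin 4: distances 3.5+/-0.3 vs 8+/-1 A and
#' 5+/-1 vs 14+/-3 A, SASA 9+/-4 vs 40+/-2 A^2.
#'
#' @param d_asp30_leu130 Named list with `closed` and `open` entries, each
#'   c(mean, sd).
#' @param d_asp35_asp129 As above.
#' @param sasa As above.
#' @return An object of class `observable_model`.
#' @export
observable_model <- function(
    d_asp30_leu130 = list(closed = c(3.5, 0.3), open = c(8, 1)),
    d_asp35_asp129 = list(closed = c(5, 1), open = c(14, 3)),
    sasa = list(closed = c(9, 4), open = c(40, 2))) {
  obs <- list(d_asp30_leu130 = d_asp30_leu130,
              d_asp35_asp129 = d_asp35_asp129,
              sasa = sasa)
  for (nm in names(obs)) {
    for (st in c("closed", "open")) {
      v <- obs[[nm]][[st]]
      if (length(v) != 2L || !all(is.finite(v)) || v[2] <= 0 || v[1] < 0)
        stop(sprintf("observable '%s' (%s) needs c(mean >= 0, sd > 0)", nm, st),
             call. = FALSE)
    }
  }
  structure(obs, class = "observable_model")
}

#' Simulator state
#'
#' One of the four species of the cycle, encoded as a conformation label
#' and a protonation flag.
#'
#' @param conformation `"closed"` or `"open"`.
#' @param protonated Logical.
#' @return An object of class `sim_state` with a `species` field in
#'   CH / C- / OpH / Op-.
#' @export
sim_state <- function(conformation = c("closed", "open"), protonated = TRUE) {
  conformation <- match.arg(conformation)
  protonated <- isTRUE(protonated)
  species <- if (conformation == "closed") {
    if (protonated) "CH" else "C-"
  } else {
    if (protonated) "OpH" else "Op-"
  }
  structure(list(conformation = conformation, protonated = protonated,
                 species = species),
            class = "sim_state")
}

#' Metropolis acceptance probability of a protonation flip
#'
#' For deprotonation the free-energy change in kT units is
#' `ln(10) * (pK_conf - pH)`, where pK_conf is the microscopic pKa of the
#' current conformation; the reverse move negates it. The acceptance is
#' `min(1, exp(-dG/kT))`, i.e. `min(1, 10^(pH - pK_conf))` for
#' deprotonation. Within a fixed conformation the stationary
#' deprotonated:protonated ratio is therefore `10^(pH - pK_conf)` — the
#' Henderson-Hasselbalch law.
#'
#' @param state A [sim_state()].
#' @param cycle A [thermo_cycle()].
#' @param ph Solvent pH.
#' @return Acceptance probability in (0, 1].
#' @export
protonation_acceptance <- function(state, cycle, ph) {
  cycle <- as_thermo_cycle(cycle)
  pk <- if (state$conformation == "closed") cycle$pk_closed else cycle$pk_open
  if (state$protonated) min(1, 10^(ph - pk)) else min(1, 10^(pk - ph))
}

#' Metropolis acceptance probability of a conformational flip
#'
#' At fixed protonation the closed->open free-energy change in kT units is
#' `-ln K`, with K = K_H when protonated and K = K_D when deprotonated, so
#' the acceptance is `min(1, K)` for opening and `min(1, 1/K)` for
#' closing. Jointly with [protonation_acceptance()] this satisfies
#' detailed balance with respect to the four-state equilibrium.
#'
#' @inheritParams protonation_acceptance
#' @return Acceptance probability in (0, 1].
#' @export
conformation_acceptance <- function(state, cycle) {
  cycle <- as_thermo_cycle(cycle)
  k <- if (state$protonated) cycle$kh else cycle$kd
  if (state$conformation == "closed") min(1, k) else min(1, 1 / k)
}

#' Single Metropolis protonation move
#'
#' Proposes flipping the protonation state and accepts with
#' [protonation_acceptance()]. Draws one uniform variate from the global
#' RNG stream.
#'
#' @inheritParams protonation_acceptance
#' @return The (possibly updated) `sim_state`.
#' @export
protonation_step <- function(state, cycle, ph) {
  if (stats::runif(1) < protonation_acceptance(state, cycle, ph))
    sim_state(state$conformation, !state$protonated)
  else state
}

#' Single Metropolis conformational move
#'
#' Proposes flipping the conformation at fixed protonation and accepts
#' with [conformation_acceptance()].
#'
#' @inheritParams protonation_acceptance
#' @return The (possibly updated) `sim_state`.
#' @export
conformation_step <- function(state, cycle) {
  if (stats::runif(1) < conformation_acceptance(state, cycle))
    sim_state(if (state$conformation == "closed") "open" else "closed",
              state$protonated)
  else state
}

#' Simulate a coupled protonation/conformation trajectory
#'
#' Runs the discrete-time Metropolis chain (compiled core) and emits one
#' frame per step with observables drawn from the conformation-conditioned
#' Gaussians of the [observable_model()] (SASA truncated at zero by
#' resampling). The result emulates the per-frame output of a constant-pH
#' MD run: a time series of conformation, protonation state and monitored
#' structural observables whose stationary statistics follow the
#' four-state equilibrium at the given pH. Fully reproducible given
#' `kin$seed`; the caller's RNG state is untouched.
#'
#' @inheritParams protonation_acceptance
#' @param kin A [kinetic_params()].
#' @param obs An [observable_model()].
#' @param start A [sim_state()] giving the initial species (default
#'   closed, protonated — the low-pH resting state).
#' @param step_ns Nominal time per frame in ns (default 0.001, i.e. one
#'   frame per picosecond).
#' @return A data.frame of class `cphmd_trajectory` with columns
#'   `time_ns`, `conformation`, `protonated`, `d_asp30_leu130`,
#'   `d_asp35_asp129`, `sasa`, and attributes `ph`, `seed`, `step_ns`,
#'   `burn_in` and `cycle`.
#' @examples
#' cyc <- thermo_cycle()
#' tr <- simulate_cphmd(cyc, ph = 5.5, kin = kinetic_params(n_steps = 2000))
#' mean(tr$conformation == "open")
#' @export
simulate_cphmd <- function(cycle, ph, kin = kinetic_params(),
                           obs = observable_model(),
                           start = sim_state("closed", TRUE),
                           step_ns = 0.001) {
  cycle <- as_thermo_cycle(cycle)
  stopifnot(inherits(kin, "kinetic_params"), inherits(obs, "observable_model"),
            inherits(start, "sim_state"), is.finite(ph))
  frames <- with_local_seed(kin$seed, {
    chain <- simulate_chain_cpp(cycle$pk_closed, cycle$pk_open,
                                cycle$kd, cycle$kh, ph,
                                kin$n_steps, kin$mc_interval,
                                kin$p_conf_attempt,
                                as.integer(start$conformation == "open"),
                                as.integer(start$protonated))
    is_open <- chain$open == 1L
    emit <- function(par) {
      mu <- ifelse(is_open, par$open[1], par$closed[1])
      sd <- ifelse(is_open, par$open[2], par$closed[2])
      stats::rnorm(kin$n_steps, mu, sd)
    }
    d1 <- emit(obs$d_asp30_leu130)
    d2 <- emit(obs$d_asp35_asp129)
    sa <- emit(obs$sasa)
    # truncate SASA at 0 by resampling the offending frames
    bad <- which(sa < 0)
    while (length(bad) > 0L) {
      mu <- ifelse(is_open[bad], obs$sasa$open[1], obs$sasa$closed[1])
      sd <- ifelse(is_open[bad], obs$sasa$open[2], obs$sasa$closed[2])
      sa[bad] <- stats::rnorm(length(bad), mu, sd)
      bad <- bad[sa[bad] < 0]
    }
    data.frame(
      time_ns = seq_len(kin$n_steps) * step_ns,
      conformation = ifelse(is_open, "open", "closed"),
      protonated = chain$protonated,
      d_asp30_leu130 = d1, d_asp35_asp129 = d2, sasa = sa
    )
  })
  structure(frames,
            ph = ph, seed = kin$seed, step_ns = step_ns,
            burn_in = kin$burn_in,
            cycle = unclass(cycle)[c("pk_closed", "pk_open", "kd", "kh")],
            class = c("cphmd_trajectory", "data.frame"))
}

#' Post-burn-in species frequencies of a trajectory
#'
#' @param traj A `cphmd_trajectory`.
#' @param burn_in Fraction of initial frames discarded; defaults to the
#'   trajectory's `burn_in` attribute (or 0.1).
#' @return Named numeric vector of empirical mole fractions
#'   `c(x_ch, x_cm, x_oph, x_opm)`.
#' @export
species_frequencies <- function(traj, burn_in = NULL) {
  stopifnot(is.data.frame(traj),
            all(c("conformation", "protonated") %in% names(traj)))
  if (is.null(burn_in)) burn_in <- attr(traj, "burn_in") %||% 0.1
  keep <- seq_len(nrow(traj)) > floor(burn_in * nrow(traj))
  cf <- traj$conformation[keep]
  pr <- traj$protonated[keep] == 1L
  n <- sum(keep)
  c(x_ch = sum(cf == "closed" & pr) / n,
    x_cm = sum(cf == "closed" & !pr) / n,
    x_oph = sum(cf == "open" & pr) / n,
    x_opm = sum(cf == "open" & !pr) / n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synthetic titration experiment across a pH grid
#'
#' Runs one independent simulation per pH value (the seed of run i is
#' `base seed + i - 1`, so each run is individually reproducible) and
#' tallies post-burn-in protonation counts overall and per conformation —
#' the inputs the estimation routines need to recover the microscopic pKa
#' values and the conformational constant.
#'
#' @inheritParams simulate_cphmd
#' @param ph_grid Numeric vector of pH values (distinct).
#' @param keep_trajectories Keep the full per-pH trajectories in the
#'   result? Off by default to bound memory for long runs.
#' @return A list with elements `titration` (data.frame `ph`, `n_prot`,
#'   `n_total`), `by_conformation` (data.frame `ph`, `conformation`,
#'   `n_prot`, `n_total`) and `trajectories` (list of `cphmd_trajectory`
#'   or NULL).
#' @export
titration_experiment <- function(cycle, ph_grid, kin = kinetic_params(),
                                 obs = observable_model(),
                                 keep_trajectories = FALSE) {
  cycle <- as_thermo_cycle(cycle)
  stopifnot(is.numeric(ph_grid), length(ph_grid) >= 1L,
            all(is.finite(ph_grid)), !anyDuplicated(ph_grid))
  overall <- vector("list", length(ph_grid))
  by_conf <- vector("list", length(ph_grid))
  trajs <- if (keep_trajectories) vector("list", length(ph_grid)) else NULL
  for (i in seq_along(ph_grid)) {
    kin_i <- kinetic_params(n_steps = kin$n_steps,
                            mc_interval = kin$mc_interval,
                            p_conf_attempt = kin$p_conf_attempt,
                            seed = kin$seed + i - 1L,
                            burn_in = kin$burn_in)
    tr <- simulate_cphmd(cycle, ph_grid[i], kin_i, obs)
    keep <- seq_len(nrow(tr)) > floor(kin$burn_in * nrow(tr))
    cf <- tr$conformation[keep]; pr <- tr$protonated[keep]
    overall[[i]] <- data.frame(ph = ph_grid[i], n_prot = sum(pr),
                               n_total = sum(keep))
    by_conf[[i]] <- data.frame(
      ph = ph_grid[i],
      conformation = c("closed", "open"),
      n_prot = c(sum(pr[cf == "closed"]), sum(pr[cf == "open"])),
      n_total = c(sum(cf == "closed"), sum(cf == "open"))
    )
    if (keep_trajectories) trajs[[i]] <- tr
  }
  list(titration = do.call(rbind, overall),
       by_conformation = do.call(rbind, by_conf),
       trajectories = trajs)
}
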