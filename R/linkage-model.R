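#' Four-state thermodynamic cycle for a pH-coupled conformational switch
#'
#' Constructs the four-state model linking the protonation state of a single
#' titratable residue to a two-state (closed/open) conformational
#' equilibrium. The four species are CH (closed, protonated), C- (closed,
#' deprotonated), OpH (open, protonated) and Op- (open, deprotonated). The
#' vertical equilibria are acid dissociations governed by the microscopic
#' pKa of the residue in each conformation; the horizontal equilibria are
#' the conformational constants K_H = (OpH)/(CH) and K_D = (Op-)/(C-).
#' Cycle closure fixes K_H once the two pKa values and K_D are given:
#' `K_H = K_D * 10^(pK_open - pK_closed)`.
#'
#' @param pk_closed Microscopic pKa of the residue in the closed
#'   conformation (dimensionless). Default 8.5, the buried-carboxylate
#'   value for Asp30 of nitrophorin 4.
#' @param pk_open Microscopic pKa in the open conformation. Default 4.3,
#'   close to the solution value of an exposed aspartate.
#' @param kd Conformational equilibrium constant (Op-)/(C-) for the
#'   deprotonated residue; must be positive. Default 100.
#' @return An object of class `thermo_cycle`: a list with elements
#'   `pk_closed`, `pk_open`, `kd` and the derived `kh`.
#' @examples
#' cyc <- thermo_cycle(8.5, 4.3, kd = 100)
#' cyc$kh # 6.31e-3
#' @export
thermo_cycle <- function(pk_closed = 8.5, pk_open = 4.3, kd = 100) {
  stopifnot(is.numeric(pk_closed), length(pk_closed) == 1L, is.finite(pk_closed),
            is.numeric(pk_open), length(pk_open) == 1L, is.finite(pk_open),
            is.numeric(kd), length(kd) == 1L)
  if (!is.finite(kd) || kd <= 0)
    stop("'kd' must be a positive finite equilibrium constant", call. = FALSE)
  structure(
    list(pk_closed = as.numeric(pk_closed),
         pk_open = as.numeric(pk_open),
         kd = as.numeric(kd),
         kh = derive_kh(pk_closed, pk_open, kd)),
    class = "thermo_cycle"
  )
}

#' @export
print.thermo_cycle <- function(x, ...) {
  cat("Four-state proton-linkage cycle\n")
  cat(sprintf("  pKa (closed): %.3g   pKa (open): %.3g\n", x$pk_closed, x$pk_open))
  cat(sprintf("  K_D (Op-/C-): %.4g   K_H (OpH/CH): %.4g\n", x$kd, x$kh))
  cat(sprintf("  apparent pKa of the transition: %.3f\n", apparent_pka(x)))
  invisible(x)
}

#' Conformational constant of the protonated species from cycle closure
#'
#' The four equilibrium constants of the cycle are not independent: going
#' around the loop CH -> C- -> Op- -> OpH -> CH must leave the free energy
#' unchanged, which forces `K_H = K_D * 10^(pk_open - pk_closed)`.
#'
#' @inheritParams thermo_cycle
#' @return The conformational constant K_H = (OpH)/(CH), dimensionless.
#' @examples
#' derive_kh(8.5, 4.3, 100) # 6.31e-3
#' @export
derive_kh <- function(pk_closed, pk_open, kd) {
  stopifnot(is.finite(pk_closed), is.finite(pk_open))
  if (!is.numeric(kd) || !is.finite(kd) || kd <= 0)
    stop("'kd' must be a positive finite equilibrium constant", call. = FALSE)
  kd * 10^(pk_open - pk_closed)
}

as_thermo_cycle <- function(x) {
  if (inherits(x, "thermo_cycle")) return(x)
  stop("expected a 'thermo_cycle' object; see thermo_cycle()", call. = FALSE)
}

#' Equilibrium mole fractions of the four species at a given pH
#'
#' Solves the mass balance of the cycle analytically. Relative to CH, the
#' Boltzmann weights of the species are 1 (CH), K_H (OpH), u (C-) and
#' K_D*u (Op-), with u = 10^(pH - pk_closed). Weights are evaluated in log
#' space and rescaled by the largest exponent before normalisation, so the
#' computation is overflow-safe at arbitrarily extreme pH.
#'
#' @param cycle A [thermo_cycle()].
#' @param ph Numeric vector of pH values (finite).
#' @return A data.frame with one row per pH and columns `ph`, `x_ch`,
#'   `x_cm`, `x_oph`, `x_opm` (mole fractions summing to 1), plus the
#'   conformational marginals `x_closed` and `x_open`.
#' @examples
#' populations(thermo_cycle(), ph = 5.5) # open fraction ~ 0.096
#' @export
populations <- function(cycle, ph) {
  cycle <- as_thermo_cycle(cycle)
  stopifnot(is.numeric(ph), length(ph) >= 1L, all(is.finite(ph)))
  ln10 <- log(10)
  # log-weights relative to CH
  lw <- cbind(
    x_ch  = 0,
    x_cm  = ln10 * (ph - cycle$pk_closed),
    x_oph = log(cycle$kh),
    x_opm = log(cycle$kd) + ln10 * (ph - cycle$pk_closed)
  )
  m <- apply(lw, 1L, max)
  w <- exp(lw - m)
  frac <- w / rowSums(w)
  out <- data.frame(
    ph = ph,
    x_ch = frac[, "x_ch"], x_cm = frac[, "x_cm"],
    x_oph = frac[, "x_oph"], x_opm = frac[, "x_opm"]
  )
  out$x_closed <- out$x_ch + out$x_cm
  out$x_open <- out$x_oph + out$x_opm
  out
}

#' Species populations along a pH grid
#'
#' Element-wise [populations()] over a strictly increasing pH grid, the
#' form used for population-vs-pH diagrams.
#'
#' @inheritParams populations
#' @param ph_grid Strictly increasing numeric vector of pH values.
#' @return A data.frame as from [populations()], one row per grid point.
#' @export
population_curve <- function(cycle, ph_grid) {
  stopifnot(is.numeric(ph_grid), length(ph_grid) >= 1L, all(is.finite(ph_grid)))
  if (is.unsorted(ph_grid, strictly = TRUE))
    stop("'ph_grid' must be strictly increasing", call. = FALSE)
  populations(cycle, ph_grid)
}

#' Two-plateau signal model for a conformation-sensitive observable
#'
#' Describes an observable whose value depends only on the conformation:
#' `alpha` in the closed state, `beta` in the open state. The measured
#' ensemble signal is the population-weighted average of the two plateaus.
#' Defaults are the plateaus of the NO dissociation constant of
#' nitrophorin 4 versus pH (alpha = 0.03 closed, beta = 0.55 open).
#'
#' @param alpha Limiting signal of the closed conformation.
#' @param beta Limiting signal of the open conformation; must differ from
#'   `alpha`, otherwise the signal carries no conformational information.
#' @return An object of class `signal_model`.
#' @export
signal_model <- function(alpha = 0.03, beta = 0.55) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(beta), length(beta) == 1L, is.finite(beta))
  if (alpha == beta)
    stop("'alpha' and 'beta' must differ: equal plateaus carry no conformational signal",
         call. = FALSE)
  structure(list(alpha = alpha, beta = beta), class = "signal_model")
}

#' Ensemble signal as a function of pH
#'
#' Population-weighted average of the conformational plateaus,
#' `alpha * x_closed(pH) + beta * x_open(pH)`. Sigmoidal in pH with
#' inflection at the apparent pKa of the transition.
#'
#' @inheritParams populations
#' @param sig A [signal_model()].
#' @return Numeric vector of signal values, one per pH.
#' @export
signal <- function(cycle, sig, ph) {
  stopifnot(inherits(sig, "signal_model"))
  pop <- populations(cycle, ph)
  sig$alpha * pop$x_closed + sig$beta * pop$x_open
}

open_fraction_limits <- function(cycle) {
  c(low = cycle$kh / (1 + cycle$kh), high = cycle$kd / (1 + cycle$kd))
}

#' Apparent pKa of the conformational transition (closed form)
#'
#' The open fraction is a logistic function of pH whose midpoint —
#' equivalently, the inflection point of any affine signal built on it —
#' lies at `pk_closed + log10((1 + K_H) / (1 + K_D))`. This is the single
#' pH midpoint an experiment reports, and it is bounded by the two
#' microscopic pKa values whenever K_H <= 1 <= K_D.
#'
#' @inheritParams populations
#' @return The apparent pKa (dimensionless pH value).
#' @examples
#' apparent_pka(thermo_cycle(8.5, 4.3, 100)) # ~ 6.5
#' @export
apparent_pka <- function(cycle) {
  cycle <- as_thermo_cycle(cycle)
  # In the fully symmetric limit K_H = K_D the open fraction is flat and no
  # inflection exists, but the closed form degrades gracefully to the single
  # microscopic pKa, so no degeneracy error is raised here (contrast
  # apparent_pka_numeric, which has nothing to locate).
  cycle$pk_closed + log10((1 + cycle$kh) / (1 + cycle$kd))
}

#' Apparent pKa by numeric inflection of the signal curve
#'
#' Locates the root of the second derivative of the signal-vs-pH curve by
#' sign-change bracketing and bisection to |dpH| <= 1e-6 on
#' `[pk_open - 4, pk_closed + 4]`. Serves as the independent check on the
#' closed form of [apparent_pka()]; the two agree because the open
#' fraction is an exact logistic in pH.
#'
#' @inheritParams signal
#' @return The inflection pH.
#' @export
apparent_pka_numeric <- function(cycle, sig = signal_model()) {
  cycle <- as_thermo_cycle(cycle)
  stopifnot(inherits(sig, "signal_model"))
  lim <- open_fraction_limits(cycle)
  if (abs(lim["high"] - lim["low"]) <= 1e-9)
    stop("transition undefined: open-fraction limits coincide", call. = FALSE)
  # h large enough that the centred second difference is not cancellation-
  # limited even for near-flat sigmoids (tiny plateau separation); for a
  # logistic the inflection location bias of the discretisation is O(h^4),
  # far below the 1e-6 bisection tolerance
  h <- 1e-2
  d2 <- function(ph) {
    s <- signal(cycle, sig, c(ph - h, ph, ph + h))
    (s[1] - 2 * s[2] + s[3]) / h^2
  }
  lo <- min(cycle$pk_open, cycle$pk_closed) - 4
  hi <- max(cycle$pk_open, cycle$pk_closed) + 4
  grid <- seq(lo, hi, length.out = 513L)
  s <- signal(cycle, sig, grid)
  # the inflection sits at the extremum of the first derivative; bracketing
  # there avoids the spurious finite-difference sign flips of the nearly
  # flat sigmoid tails
  d1 <- abs(s[-1] - s[-length(s)])
  m <- which.max(d1) # slope extremum lies in (grid[m], grid[m+1])
  a <- grid[max(1L, m - 1L)]
  b <- grid[min(length(grid), m + 2L)]
  fa <- d2(a); fb <- d2(b)
  if (m == 1L || m == length(d1) || !is.finite(fa) || !is.finite(fb) ||
      sign(fa) * sign(fb) >= 0)
    stop("transition undefined: no inflection found in bracket", call. = FALSE)
  while (b - a > 1e-6) {
    mid <- (a + b) / 2
    fm <- d2(mid)
    if (fm == 0) return(mid)
    if (sign(fm) == sign(fa)) { a <- mid; fa <- fm } else b <- mid
  }
  (a + b) / 2
}

#' Scan the conformational constant K_D
#'
#' Tabulates, for each K_D on a grid, the derived K_H, the apparent pKa of
#' the transition, and the two populations that measure biological
#' efficiency of a pH switch: the closed-protonated-dominant fraction
#' x_CH at a low working pH and the open-deprotonated fraction x_Op- at a
#' high working pH.
#'
#' @inheritParams thermo_cycle
#' @param kd_grid Positive numeric vector of K_D values.
#' @param ph_low,ph_high The two working pH values (defaults 5.5, 7.5).
#' @return A data.frame with columns `kd`, `kh`, `pka_app`, `x_ch_low`,
#'   `x_opm_high`.
#' @export
kd_scan <- function(pk_closed = 8.5, pk_open = 4.3, kd_grid,
                    ph_low = 5.5, ph_high = 7.5) {
  stopifnot(is.numeric(kd_grid), length(kd_grid) >= 1L)
  if (any(!is.finite(kd_grid) | kd_grid <= 0))
    stop("'kd_grid' entries must be positive and finite", call. = FALSE)
  rows <- lapply(kd_grid, function(kd) {
    cyc <- thermo_cycle(pk_closed, pk_open, kd)
    data.frame(
      kd = kd, kh = cyc$kh,
      pka_app = apparent_pka(cyc),
      x_ch_low = populations(cyc, ph_low)$x_ch,
      x_opm_high = populations(cyc, ph_high)$x_opm
    )
  })
  do.call(rbind, rows)
}

#' K_D that maximises switching efficiency
#'
#' Finds the K_D maximising `min(x_CH at ph_low, x_Op- at ph_high)`. The
#' first fraction decreases and the second increases strictly in K_D, so
#' the maximiser is their unique crossing, located by root finding on
#' log10 K_D over [-2, 6] to a tolerance of 1e-4 log units.
#'
#' @inheritParams kd_scan
#' @return A list with the optimal `kd` and the common fraction `objective`
#'   attained by both populations at the optimum.
#' @export
optimal_kd <- function(pk_closed = 8.5, pk_open = 4.3,
                       ph_low = 5.5, ph_high = 7.5) {
  stopifnot(ph_low < ph_high)
  gap <- function(lk) {
    cyc <- thermo_cycle(pk_closed, pk_open, 10^lk)
    populations(cyc, ph_low)$x_ch - populations(cyc, ph_high)$x_opm
  }
  root <- stats::uniroot(gap, interval = c(-2, 6), tol = 1e-4)$root
  kd <- 10^root
  cyc <- thermo_cycle(pk_closed, pk_open, kd)
  list(kd = kd,
       objective = min(populations(cyc, ph_low)$x_ch,
                       populations(cyc, ph_high)$x_opm))
}

#' Range of K_D keeping the minority species insignificant
#'
#' A working pH switch requires that neither off-pathway species — C-
#' (deprotonated but still closed) at high pH, OpH (protonated but open)
#' at low pH — ever becomes significant. In `"asymptotic"` mode the
#' limiting fractions are the closed forms x_C- -> 1/(1 + K_D) as pH ->
#' +Inf and x_OpH -> K_H/(1 + K_H) as pH -> -Inf, giving
#' `kd_min = 1/threshold - 1` and `kd_max` from `K_H/(1+K_H) = threshold`.
#' In `"fixed"` mode the same fractions are evaluated at the two supplied
#' pH values and the bounds found numerically.
#'
#' @inheritParams kd_scan
#' @param threshold Maximum tolerated mole fraction of either off-pathway
#'   species, in (0, 0.5).
#' @param mode `"asymptotic"` (default) or `"fixed"`.
#' @return Named numeric vector `c(kd_min, kd_max)`.
#' @export
valid_kd_range <- function(pk_closed = 8.5, pk_open = 4.3, threshold = 0.10,
                           mode = c("asymptotic", "fixed"),
                           ph_low = 5.5, ph_high = 7.5) {
  mode <- match.arg(mode)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 0.5)
    stop("'threshold' must lie in (0, 0.5)", call. = FALSE)
  if (mode == "asymptotic") {
    kd_min <- 1 / threshold - 1
    kh_max <- threshold / (1 - threshold)
    kd_max <- kh_max * 10^(pk_closed - pk_open)
  } else {
    f_cm <- function(lk)
      populations(thermo_cycle(pk_closed, pk_open, 10^lk), ph_high)$x_cm - threshold
    f_oph <- function(lk)
      populations(thermo_cycle(pk_closed, pk_open, 10^lk), ph_low)$x_oph - threshold
    # x_cm(ph_high) decreases in K_D; if it is below threshold even for
    # vanishing K_D the lower constraint never binds (kd_min = 0), and
    # symmetrically for x_oph(ph_low) and the upper constraint.
    kd_min <- if (f_cm(-6) <= 0) 0
      else 10^stats::uniroot(f_cm, c(-6, 8), tol = 1e-6)$root
    kd_max <- if (f_oph(8) <= 0) Inf
      else 10^stats::uniroot(f_oph, c(-6, 8), tol = 1e-6)$root
  }
  c(kd_min = kd_min, kd_max = kd_max)
}
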