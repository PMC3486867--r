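#' pKa estimate container
#'
#' @param pka Point estimate (NA when censored).
#' @param hill Hill coefficient (1 when fixed).
#' @param stderr Standard error (NA when unavailable or censored).
#' @param n Number of observations behind the estimate.
#' @param method Label: "single-pH inversion" or "multi-pH fit".
#' @param censored One of "none", "lower" (pKa < bound), "upper"
#'   (pKa > bound), or "empty" (no observations).
#' @param bound The censoring bound (the pH), NA when not censored.
#' @return An object of class `pka_estimate`.
#' @keywords internal
new_pka_estimate <- function(pka, hill = 1, stderr = NA_real_, n = 0L,
                             method = "single-pH inversion",
                             censored = "none", bound = NA_real_) {
  structure(list(pka = pka, hill = hill, stderr = stderr,
                 n = as.integer(n), method = method,
                 censored = censored, bound = bound),
            class = "pka_estimate")
}

#' @export
print.pka_estimate <- function(x, ...) {
  if (x$censored == "none") {
    cat(sprintf("pKa = %.3f (se %.3f, n = %d, %s)\n",
                x$pka, x$stderr, x$n, x$method))
  } else if (x$censored == "empty") {
    cat("pKa estimate: no observations\n")
  } else {
    cat(sprintf("pKa %s %.2f (censored, n = %d)\n",
                if (x$censored == "lower") "<" else ">", x$bound, x$n))
  }
  invisible(x)
}

#' Microscopic pKa from a protonated fraction at one pH
#'
#' Henderson-Hasselbalch inversion: with protonated fraction
#' f = n_protonated / n_total strictly inside (0, 1),
#' `pKa = pH + log10(f / (1 - f))`. The standard error is propagated from
#' the binomial standard error of f assuming independent frames
#' (`1 / (ln 10 * sqrt(n f (1-f)))`); for autocorrelated trajectory data
#' see [bootstrap_ci()]. A fraction of exactly 0 or 1 only bounds the pKa,
#' so the estimate is returned censored ("pKa < pH" / "pKa > pH") rather
#' than infinite.
#'
#' @param ph Solvent pH of the observations.
#' @param n_protonated,n_total Frame counts, 0 <= n_protonated <= n_total.
#' @return A `pka_estimate`.
#' @examples
#' pka_from_counts(7.5, 909, 1000) # ~ 8.5
#' @export
pka_from_counts <- function(ph, n_protonated, n_total) {
  stopifnot(is.finite(ph), length(ph) == 1L)
  if (n_total < 0 || n_protonated < 0 || n_protonated > n_total)
    stop("counts must satisfy 0 <= n_protonated <= n_total", call. = FALSE)
  if (n_total == 0)
    return(new_pka_estimate(NA_real_, n = 0L, censored = "empty", bound = ph))
  if (n_protonated == 0)
    return(new_pka_estimate(NA_real_, n = n_total, censored = "lower", bound = ph))
  if (n_protonated == n_total)
    return(new_pka_estimate(NA_real_, n = n_total, censored = "upper", bound = ph))
  f <- n_protonated / n_total
  se <- 1 / (log(10) * sqrt(n_total * f * (1 - f)))
  new_pka_estimate(ph + log10(f / (1 - f)), stderr = se, n = n_total)
}

#' Fit a titration curve to per-pH protonation counts
#'
#' Maximises the binomial likelihood of the counts under the generalised
#' Henderson-Hasselbalch curve
#' `f(pH) = 1 / (1 + 10^(n * (pH - pKa)))`. With `fix_hill = TRUE`
#' (default, the single-ideal-site assumption) the Hill coefficient n is
#' fixed at 1 and the model is a binomial GLM with logit link and the
#' term `-ln(10) * pH` as an offset; with a free Hill coefficient the
#' slope is estimated too. Standard errors come from the likelihood
#' curvature (GLM covariance, delta method for the free-n midpoint).
#'
#' @param series A data.frame with columns `ph`, `n_prot`, `n_total`
#'   (distinct pH values; counts within totals).
#' @param fix_hill Fix the Hill coefficient at 1?
#' @return A `pka_estimate` with `method = "multi-pH fit"`.
#' @export
fit_titration <- function(series, fix_hill = TRUE) {
  stopifnot(is.data.frame(series),
            all(c("ph", "n_prot", "n_total") %in% names(series)))
  if (anyDuplicated(series$ph))
    stop("pH values in the titration series must be distinct", call. = FALSE)
  if (any(series$n_prot < 0 | series$n_prot > series$n_total | series$n_total <= 0))
    stop("counts must satisfy 0 <= n_prot <= n_total, n_total > 0", call. = FALSE)
  f <- series$n_prot / series$n_total
  informative <- sum(f > 0 & f < 1)
  needed <- if (fix_hill) 1L else 3L
  if (informative < needed || (!fix_hill && sum(series$n_total > 0) < 2L))
    stop(sprintf(paste(
      "cannot fit titration curve: only %d pH point(s) have a protonated",
      "fraction strictly between 0 and 1 (need >= %d); all other points",
      "merely bound the pKa"), informative, needed), call. = FALSE)
  ln10 <- log(10)
  n_tot <- sum(series$n_total)
  if (fix_hill) {
    fit <- stats::glm(cbind(n_prot, n_total - n_prot) ~ 1 + offset(-ln10 * ph),
                      family = stats::binomial(), data = series)
    pka <- unname(stats::coef(fit)[1]) / ln10
    se <- sqrt(stats::vcov(fit)[1, 1]) / ln10
    new_pka_estimate(pka, hill = 1, stderr = se, n = n_tot,
                     method = "multi-pH fit")
  } else {
    fit <- stats::glm(cbind(n_prot, n_total - n_prot) ~ ph,
                      family = stats::binomial(), data = series)
    a <- stats::coef(fit)[1]; b <- stats::coef(fit)[2]
    if (b >= 0)
      stop("titration fit degenerate: protonated fraction not decreasing in pH",
           call. = FALSE)
    hill <- -b / ln10
    pka <- unname(-a / b)
    # delta method for pKa = -a/b
    g <- c(-1 / b, a / b^2)
    se <- sqrt(drop(t(g) %*% stats::vcov(fit) %*% g))
    new_pka_estimate(pka, hill = unname(hill), stderr = se, n = n_tot,
                     method = "multi-pH fit")
  }
}

#' Conformation-conditioned microscopic pKa estimates from a trajectory
#'
#' Partitions post-burn-in frames by conformation label and applies
#' Henderson-Hasselbalch inversion ([pka_from_counts()]) within each
#' partition, yielding the two microscopic pKa estimates that the
#' four-state model takes as inputs. A partition with no frames yields an
#' "empty"-censored estimate.
#'
#' @param traj A trajectory data.frame (see [simulate_cphmd()]) with
#'   columns `conformation` and `protonated`, and a `ph` attribute, or a
#'   list of such trajectories at the same pH to pool.
#' @param ph Solvent pH; defaults to the trajectory's `ph` attribute.
#' @param burn_in Fraction of initial frames discarded from each
#'   trajectory before counting (default 0.1).
#' @return A list with `pka_estimate` elements `closed` and `open`.
#' @export
conditional_pka <- function(traj, ph = NULL, burn_in = 0.1) {
  trajs <- if (is.data.frame(traj)) list(traj) else traj
  stopifnot(length(trajs) >= 1L, burn_in >= 0, burn_in < 1)
  if (is.null(ph)) {
    phs <- unique(vapply(trajs, function(t) attr(t, "ph"), numeric(1)))
    if (length(phs) != 1L || !is.finite(phs))
      stop("trajectories must share a single finite 'ph' attribute, or pass 'ph'",
           call. = FALSE)
    ph <- phs
  }
  counts <- c(closed_prot = 0, closed_tot = 0, open_prot = 0, open_tot = 0)
  for (t in trajs) {
    stopifnot(all(c("conformation", "protonated") %in% names(t)))
    keep <- seq_len(nrow(t)) > floor(burn_in * nrow(t))
    cf <- t$conformation[keep]; pr <- t$protonated[keep]
    counts["closed_tot"] <- counts["closed_tot"] + sum(cf == "closed")
    counts["closed_prot"] <- counts["closed_prot"] + sum(pr[cf == "closed"])
    counts["open_tot"] <- counts["open_tot"] + sum(cf == "open")
    counts["open_prot"] <- counts["open_prot"] + sum(pr[cf == "open"])
  }
  list(closed = pka_from_counts(ph, unname(counts["closed_prot"]),
                                unname(counts["closed_tot"])),
       open = pka_from_counts(ph, unname(counts["open_prot"]),
                              unname(counts["open_tot"])))
}

#' Time-resolved pKa over a trailing window
#'
#' Converts the protonated fraction in a trailing window of frames to a
#' pKa via Henderson-Hasselbalch inversion at the trajectory pH, the
#' windowed analogue of the time-resolved pKa traces drawn under
#' transition trajectories. Entries are undefined until the window fills;
#' windows that are entirely protonated or deprotonated are censored.
#'
#' @inheritParams conditional_pka
#' @param window Window length in frames (>= 10).
#' @return A data.frame with columns `frame`, `pka` (NA where undefined or
#'   censored) and `censored` ("unfilled", "none", "lower", "upper").
#' @export
running_pka <- function(traj, window = 100L, ph = NULL) {
  stopifnot(is.data.frame(traj), "protonated" %in% names(traj))
  window <- as.integer(window)
  if (window < 10L) stop("'window' must be at least 10 frames", call. = FALSE)
  n <- nrow(traj)
  if (window > n) stop("'window' exceeds trajectory length", call. = FALSE)
  if (is.null(ph)) ph <- attr(traj, "ph")
  stopifnot(is.finite(ph))
  cs <- cumsum(traj$protonated)
  k <- window:n
  n_prot <- cs[k] - c(0, cs)[k - window + 1L]
  pka <- rep(NA_real_, n)
  cens <- rep("unfilled", n)
  f <- n_prot / window
  ok <- f > 0 & f < 1
  pka[k][ok] <- ph + log10(f[ok] / (1 - f[ok]))
  cens[k] <- ifelse(f == 0, "lower", ifelse(f == 1, "upper", "none"))
  data.frame(frame = seq_len(n), pka = pka, censored = cens)
}

#' Trailing running average of a numeric series
#'
#' Trailing mean over `window` frames; output has the length of the input
#' with the first `window - 1` entries NA (flagged unfilled), matching the
#' smoothing applied to trajectory distance traces before inspection.
#'
#' @param x Numeric series.
#' @param window Window length in frames (>= 1).
#' @return Numeric vector, same length as `x`.
#' @export
running_average <- function(x, window = 100L) {
  stopifnot(is.numeric(x))
  if (length(x) == 0L) stop("empty series", call. = FALSE)
  window <- as.integer(window)
  stopifnot(window >= 1L)
  if (window > length(x)) stop("'window' exceeds series length", call. = FALSE)
  out <- rep(NA_real_, length(x))
  cs <- cumsum(x)
  k <- window:length(x)
  out[k] <- (cs[k] - c(0, cs)[k - window + 1L]) / window
  out
}

#' Mean and sample standard deviation of an observable series
#'
#' @param x Numeric series with at least 2 values.
#' @param digits Optional rounding applied to the formatted summary
#'   (e.g. 1 to report distances as in a mean +/- sd table).
#' @return A list with `mean`, `sd`, `n`, and `label` (formatted
#'   "mean +/- sd").
#' @export
summarize_observable <- function(x, digits = 1L) {
  stopifnot(is.numeric(x))
  x <- x[is.finite(x)]
  if (length(x) < 2L) stop("need at least 2 finite values", call. = FALSE)
  m <- mean(x); s <- stats::sd(x)
  list(mean = m, sd = s, n = length(x),
       label = sprintf("%.*f±%.*f", digits, m, digits, s))
}

#' Detect a persistent transition between two reference levels
#'
#' Smooths the series with a trailing running average, then returns the
#' first frame at which the smoothed series crosses the midpoint of the
#' two reference means and remains on the far (ref_b) side for at least
#' `persistence` consecutive frames. The trailing smoothing delays the
#' detected crossing by up to `window` frames relative to the underlying
#' event; callers comparing against a known change point should allow for
#' that lag.
#'
#' @param x Numeric series (e.g. a monitored inter-residue distance).
#' @param ref_a Reference (mean, sd) of the starting regime.
#' @param ref_b Reference (mean, sd) of the destination regime; means must
#'   differ by more than the sum of the sds.
#' @param persistence Minimum number of consecutive frames beyond the
#'   midpoint (default 50).
#' @param window Running-average window (default 100 frames).
#' @return The transition frame index, or `NA_integer_` if no persistent
#'   crossing occurs.
#' @export
detect_transition <- function(x, ref_a, ref_b, persistence = 50L,
                              window = 100L) {
  stopifnot(is.numeric(x), length(ref_a) >= 2L, length(ref_b) >= 2L)
  if (abs(ref_a[1] - ref_b[1]) <= ref_a[2] + ref_b[2])
    stop("reference regimes overlap: means must differ by more than the sum of sds",
         call. = FALSE)
  persistence <- as.integer(persistence)
  stopifnot(persistence >= 1L)
  window <- min(as.integer(window), length(x))
  sm <- running_average(x, window)
  mid <- (ref_a[1] + ref_b[1]) / 2
  beyond <- if (ref_b[1] > ref_a[1]) sm > mid else sm < mid
  beyond[is.na(beyond)] <- FALSE
  r <- rle(beyond)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= persistence)
  if (length(hit) == 0L) return(NA_integer_)
  starts[hit[1]]
}

#' Moving-block bootstrap percentile confidence interval
#'
#' Resamples contiguous blocks of `block_length` frames (with replacement,
#' uniformly over all start positions) to the length of the series and
#' returns the 2.5/97.5 percentile interval of the statistic. Blocks
#' preserve short-range autocorrelation, which plain binomial or iid
#' resampling would ignore for trajectory data.
#'
#' @param x Numeric (or 0/1) series.
#' @param statistic Function of the resampled series (default `mean`).
#' @param n_boot Number of bootstrap replicates (>= 100).
#' @param block_length Block length in frames (default 100; must not
#'   exceed the series length). `block_length = 1` gives the iid
#'   bootstrap.
#' @param seed Integer seed; the interval is reproducible given the seed
#'   and the global RNG state is left untouched.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
bootstrap_ci <- function(x, statistic = mean, n_boot = 1000L,
                         block_length = 100L, seed = 1L) {
  stopifnot(is.numeric(x), length(x) >= 1L)
  n_boot <- as.integer(n_boot)
  if (n_boot < 100L) stop("'n_boot' must be at least 100", call. = FALSE)
  block_length <- as.integer(block_length)
  n <- length(x)
  if (block_length < 1L || block_length > n)
    stop("'block_length' must lie in [1, length(x)]", call. = FALSE)
  n_blocks <- ceiling(n / block_length)
  n_starts <- n - block_length + 1L
  stat <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      starts <- sample.int(n_starts, n_blocks, replace = TRUE)
      idx <- rep(starts, each = block_length) +
        rep.int(seq_len(block_length) - 1L, n_blocks)
      statistic(x[idx[seq_len(n)]])
    }, numeric(1))
  })
  stats::quantile(stat, c(0.025, 0.975), names = FALSE) |>
    stats::setNames(c("lower", "upper"))
}

#' Rebuild a thermodynamic cycle from per-species trajectory counts
#'
#' Estimates the two microscopic pKa values by binomial titration fits on
#' the conformation-conditioned counts, and K_D from the pooled ratio of
#' open to closed frames among deprotonated frames. Because
#' (Op-)/(C-) = K_D at every pH, the pooled ratio across a pH grid is an
#' unbiased estimator of K_D; K_H then follows from cycle closure.
#'
#' @param by_conformation A data.frame with columns `ph`, `conformation`,
#'   `n_prot`, `n_total` as returned by [titration_experiment()].
#' @return A list with the rebuilt `cycle` ([thermo_cycle()]) and the
#'   component estimates `pk_closed`, `pk_open` (both `pka_estimate`) and
#'   `kd`.
#' @export
recover_cycle <- function(by_conformation) {
  stopifnot(is.data.frame(by_conformation),
            all(c("ph", "conformation", "n_prot", "n_total") %in%
                  names(by_conformation)))
  cl <- by_conformation[by_conformation$conformation == "closed", ]
  op <- by_conformation[by_conformation$conformation == "open", ]
  est_cl <- fit_titration(cl[cl$n_total > 0, ])
  est_op <- fit_titration(op[op$n_total > 0, ])
  n_cm <- sum(cl$n_total - cl$n_prot)
  n_opm <- sum(op$n_total - op$n_prot)
  if (n_cm == 0L)
    stop("cannot estimate K_D: no deprotonated closed frames", call. = FALSE)
  kd_hat <- n_opm / n_cm
  list(cycle = thermo_cycle(est_cl$pka, est_op$pka, kd_hat),
       pk_closed = est_cl, pk_open = est_op, kd = kd_hat)
}
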