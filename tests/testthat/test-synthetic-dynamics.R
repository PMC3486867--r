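test_that("Metropolis acceptances satisfy detailed balance exactly", {
  for (cyc in random_cycles(20, seed = 21L)) {
    for (ph in c(3, 6.5, 10)) {
      for (conf in c("closed", "open")) {
        pk <- if (conf == "closed") cyc$pk_closed else cyc$pk_open
        a_dep <- protonation_acceptance(sim_state(conf, TRUE), cyc, ph)
        a_pro <- protonation_acceptance(sim_state(conf, FALSE), cyc, ph)
        # flux ratio equals the within-conformation Henderson-Hasselbalch
        # deprotonated : protonated ratio
        expect_equal(a_dep / a_pro, 10^(ph - pk), tolerance = 1e-12)
      }
      for (prot in c(TRUE, FALSE)) {
        k <- if (prot) cyc$kh else cyc$kd
        a_open <- conformation_acceptance(sim_state("closed", prot), cyc)
        a_close <- conformation_acceptance(sim_state("open", prot), cyc)
        expect_equal(a_open / a_close, k, tolerance = 1e-12)
      }
    }
  }
  cyc <- ref_cycle()
  # closed at pH 5.5 with pKa 8.5: deprotonation acceptance 10^-3
  expect_equal(protonation_acceptance(sim_state("closed", TRUE), cyc, 5.5),
               1e-3)
  # at pH = pKa both directions are certain
  expect_equal(protonation_acceptance(sim_state("closed", TRUE), cyc, 8.5), 1)
  expect_equal(protonation_acceptance(sim_state("closed", FALSE), cyc, 8.5), 1)
  # protonated opening is rare (K_H), deprotonated opening certain (K_D > 1)
  expect_equal(conformation_acceptance(sim_state("closed", TRUE), cyc),
               cyc$kh)
  expect_equal(conformation_acceptance(sim_state("open", TRUE), cyc), 1)
  expect_equal(conformation_acceptance(sim_state("closed", FALSE), cyc), 1)
  sym <- thermo_cycle(7, 7, 1)
  expect_equal(conformation_acceptance(sim_state("closed", TRUE), sym), 1)
  expect_equal(conformation_acceptance(sim_state("open", TRUE), sym), 1)
})

test_that("single-step moves flip states according to the acceptances", {
  cyc <- ref_cycle()
  s <- sim_state("closed", TRUE)
  expect_identical(s$species, "CH")
  expect_identical(sim_state("open", FALSE)$species, "Op-")
  # deprotonated closed state must open on proposal (acceptance 1)
  got <- with_seed_local(22L, conformation_step(sim_state("closed", FALSE), cyc))
  expect_identical(got$conformation, "open")
  # at pH = pKa a protonation proposal always flips
  got2 <- with_seed_local(23L, protonation_step(sim_state("closed", TRUE), cyc, 8.5))
  expect_false(got2$protonated)
})

test_that("a frozen conformation titrates by Henderson-Hasselbalch", {
  cyc <- ref_cycle()
  kin <- kinetic_params(n_steps = 1e6, p_conf_attempt = 0, seed = 31L)
  tr <- simulate_cphmd(cyc, ph = 7.5, kin, start = sim_state("open", FALSE))
  expect_true(all(tr$conformation == "open"))
  f <- mean(tr$protonated)
  f_hh <- 10^(4.3 - 7.5) / (1 + 10^(4.3 - 7.5)) # ~ 6.3e-4
  expect_lt(abs(f - f_hh), 2.5e-4)
})

test_that("simulated species frequencies approach the analytic populations", {
  cyc <- ref_cycle()
  for (ph in c(5.5, 7.5)) {
    tr <- simulate_cphmd(cyc, ph, kinetic_params(n_steps = 3e5, seed = 32L))
    keep <- seq_len(nrow(tr)) > 3e4
    emp <- species_frequencies(tr)
    ana <- populations(cyc, ph)
    for (sp in c("x_ch", "x_cm", "x_oph", "x_opm")) {
      ind <- as.numeric(
        (tr$conformation[keep] == if (sp %in% c("x_ch", "x_cm")) "closed" else "open") &
          (tr$protonated[keep] == if (sp %in% c("x_ch", "x_oph")) 1L else 0L))
      se <- max(batch_se(ind), 1e-4)
      expect_lt(abs(emp[[sp]] - ana[[sp]]), 3 * se)
    }
  }
})

test_that("trajectories are reproducible and respect the observable model", {
  cyc <- ref_cycle()
  kin <- kinetic_params(n_steps = 2e4, seed = 33L)
  t1 <- simulate_cphmd(cyc, 6.5, kin)
  t2 <- simulate_cphmd(cyc, 6.5, kin)
  expect_identical(t1, t2)
  t3 <- simulate_cphmd(cyc, 6.5, kinetic_params(n_steps = 2e4, seed = 34L))
  expect_false(identical(t1$conformation, t3$conformation))
  # simulation does not disturb the caller's RNG stream
  before <- with_seed_local(35L, stats::runif(1))
  set.seed(35L)
  invisible(simulate_cphmd(cyc, 6.5, kin))
  expect_identical(stats::runif(1), before)
  # conformation-conditioned observables match their emission parameters
  closed <- t1$conformation == "closed"
  n_cl <- sum(closed)
  s <- summarize_observable(t1$d_asp30_leu130[closed])
  expect_lt(abs(s$mean - 3.5), 3 * 0.3 / sqrt(n_cl))
  expect_equal(s$sd, 0.3, tolerance = 0.05)
  # open-state emission, on a frozen all-open run for a clean CLT check
  t_open <- simulate_cphmd(cyc, 7.5,
                           kinetic_params(n_steps = 2e4, p_conf_attempt = 0,
                                          seed = 33L),
                           start = sim_state("open", FALSE))
  s2 <- summarize_observable(t_open$d_asp30_leu130)
  expect_lt(abs(s2$mean - 8), 3 * 1 / sqrt(nrow(t_open)))
  expect_equal(s2$sd, 1, tolerance = 0.05)
  # SASA is truncated at zero despite the wide closed-state Gaussian
  expect_true(all(t1$sasa >= 0))
  expect_equal(mean(t_open$sasa), 40, tolerance = 0.05)
  # time base: one frame per ps by default
  expect_equal(t1$time_ns[2] - t1$time_ns[1], 0.001)
  expect_identical(attr(t1, "ph"), 6.5)
})

test_that("deprotonation precedes opening when the closed state meets high pH", {
  # the closed-protonated resting state placed at pH 7.5 first loses the
  # proton, then opens; the hydrogen-bond distance trace moves from the
  # closed (~3.5 A) to the open (~8 A) level
  cyc <- ref_cycle()
  tr <- simulate_cphmd(cyc, 7.5, kinetic_params(n_steps = 1e5, seed = 36L))
  first_deprot <- match(0L, tr$protonated)
  first_open <- match("open", tr$conformation)
  expect_lt(first_deprot, first_open)
  hit <- detect_transition(tr$d_asp30_leu130, c(3.5, 0.3), c(8, 1),
                           persistence = 50, window = 100)
  expect_false(is.na(hit))
  expect_gte(hit, first_deprot)
  expect_equal(mean(tr$d_asp30_leu130[tr$conformation == "open"]), 8,
               tolerance = 0.1)
  # the windowed pKa trace falls from the closed value toward the open one;
  # judge the open-state level on windows that contain no closed revisits
  # (a single closed excursion injects many protonated frames)
  w <- 2000L
  rp <- running_pka(tr, window = w)
  all_open <- running_average(as.numeric(tr$conformation == "open"), w) == 1
  late <- rp$pka[!is.na(all_open) & all_open & rp$censored == "none"]
  expect_gt(length(late), 1000)
  expect_equal(mean(late), 4.3, tolerance = 0.5)
})

test_that("titration experiments tally counts per pH and per conformation", {
  cyc <- ref_cycle()
  kin <- kinetic_params(n_steps = 2e4, seed = 37L)
  single <- titration_experiment(cyc, 6.5, kin, keep_trajectories = TRUE)
  tr <- single$trajectories[[1]]
  keep <- seq_len(nrow(tr)) > floor(0.1 * nrow(tr))
  expect_equal(single$titration$n_prot, sum(tr$protonated[keep]))
  expect_equal(single$titration$n_total, sum(keep))
  expect_equal(sum(single$by_conformation$n_total), sum(keep))
  # per-pH runs are independently seeded: run i reproduces with seed + i - 1
  grid <- c(5, 6, 7)
  multi <- titration_experiment(cyc, grid, kin, keep_trajectories = TRUE)
  kin3 <- kinetic_params(n_steps = 2e4, seed = 39L) # 37 + 3 - 1
  expect_identical(as.data.frame(multi$trajectories[[3]]),
                   as.data.frame(simulate_cphmd(cyc, 7, kin3)))
  expect_error(titration_experiment(cyc, c(6, 6), kin), "anyDuplicated")
})

test_that("the aggregate titration midpoint is neither microscopic pKa", {
  # the central point of the linkage analysis: fitting one curve to the
  # pooled (conformation-blind) counts lands between the microscopic
  # values, near the apparent pKa of the transition
  cyc <- ref_cycle()
  kin <- kinetic_params(n_steps = 5e4, seed = 40L)
  exp8 <- titration_experiment(cyc, 3:10, kin)
  agg <- fit_titration(exp8$titration)
  expect_gt(agg$pka, 4.3 + 0.5)
  expect_lt(agg$pka, 8.5 - 0.5)
  # and the conformation-aware rebuild recovers the true cycle
  rec <- recover_cycle(exp8$by_conformation)
  expect_lt(abs(rec$pk_closed$pka - 8.5), 0.2)
  expect_lt(abs(rec$pk_open$pka - 4.3), 0.2)
  expect_lt(abs(log10(rec$kd) - 2), 0.2)
})
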