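# Shared fixtures: the reference cycle and a generator of random but
# physically sensible cycles (pK values in [2, 12], K_D log-uniform).

ref_cycle <- function() thermo_cycle(8.5, 4.3, 100)

random_cycles <- function(n, seed = 42L) {
  with_seed_local(seed, {
    lapply(seq_len(n), function(i) {
      pks <- sort(stats::runif(2, 2, 12))
      thermo_cycle(pk_closed = pks[2], pk_open = pks[1],
                   kd = 10^stats::runif(1, -4, 6))
    })
  })
}

# local-seed evaluation for test fixtures (keeps tests order-independent)
with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# Monte Carlo standard error of a mean over an autocorrelated 0/1 or numeric
# series, by non-overlapping batch means.
batch_se <- function(x, n_batches = 20L) {
  n <- length(x)
  bl <- floor(n / n_batches)
  means <- vapply(seq_len(n_batches), function(b)
    mean(x[((b - 1L) * bl + 1L):(b * bl)]), numeric(1))
  stats::sd(means) / sqrt(n_batches)
}
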