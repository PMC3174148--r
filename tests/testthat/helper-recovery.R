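# The parameter-recovery and rank-stabilization checks share one long run
# on the canonical fixture; it is computed lazily once per test session.

.recovery_cache <- new.env(parent = emptyenv())

recovery_config <- function(max_iters, rho_stop = 1) {
  ppea_config(alpha = 0.2, beta = 0.5, genes_per_iter = 8,
              max_iters = max_iters, checkpoint_every = 5000,
              rho_stop = rho_stop, seed = 1)
}

# Exactly 20,000 iterations on the standard fixture.
recovery_fit_20k <- function() {
  if (is.null(.recovery_cache$fit20k)) {
    sim <- standard_recovery_fixture()
    .recovery_cache$fit20k <-
      run_ppea(sim$matrix, recovery_config(20000), keep_log = FALSE)
  }
  .recovery_cache$fit20k
}

# Continuation of the same run until the rank order stabilizes
# (consecutive-checkpoint Spearman rho >= 0.99), capped at 160k iterations.
recovery_fit_stabilized <- function() {
  if (is.null(.recovery_cache$fit_stab)) {
    sim <- standard_recovery_fixture()
    .recovery_cache$fit_stab <-
      run_ppea(sim$matrix, recovery_config(160000, rho_stop = 0.99),
               state = recovery_fit_20k(), keep_log = FALSE)
  }
  .recovery_cache$fit_stab
}
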