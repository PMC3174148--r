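test_that("bootstrap draws have the documented shapes and disjointness", {
  sim <- simulate_two_class(P = 100, n_pos = 20, n_neg = 20, q = 0, seed = 2)
  cfg <- ppea_config(genes_per_iter = 10, beta = 0.5, seed = 2)
  bs <- withr::with_seed(2, draw_bootstrap(sim$matrix, cfg))
  expect_length(bs$gene_indices, 10)
  expect_length(unique(bs$gene_indices), 10)   # without replacement
  expect_length(bs$train_pos, 10); expect_length(bs$train_neg, 10)
  expect_length(bs$test_pos, 10); expect_length(bs$test_neg, 10)
  expect_length(intersect(c(bs$train_pos, bs$train_neg),
                          c(bs$test_pos, bs$test_neg)), 0)

  # minimal case: 2+2 samples, beta = 1/2, one gene
  mini <- simulate_two_class(P = 5, n_pos = 2, n_neg = 2, q = 0, seed = 3)
  cfgm <- ppea_config(genes_per_iter = 1, seed = 3)
  bm <- withr::with_seed(3, draw_bootstrap(mini$matrix, cfgm))
  expect_length(bm$train_pos, 1); expect_length(bm$test_pos, 1)
  expect_length(bm$train_neg, 1); expect_length(bm$test_neg, 1)
})

test_that("a config with too many genes per iteration is rejected", {
  sim <- simulate_two_class(P = 50, n_pos = 10, n_neg = 10, q = 0, seed = 4)
  cfg <- ppea_config(genes_per_iter = 10, seed = 1)  # needs < 5 + 5
  expect_error(draw_bootstrap(sim$matrix, cfg), "training sample count")
})

test_that("gene draw counts stay inside the exact binomial envelope", {
  sim <- simulate_two_class(P = 50, n_pos = 20, n_neg = 20, q = 0, seed = 5)
  cfg <- ppea_config(genes_per_iter = 5, seed = 5)
  cnt <- integer(50)
  withr::with_seed(11, {
    for (i in 1:10000) {
      g <- draw_bootstrap(sim$matrix, cfg)$gene_indices
      cnt[g] <- cnt[g] + 1L
    }
  })
  iv <- qbinom(c(0.0005, 0.9995), 10000, 5 / 50)
  expect_true(all(cnt >= iv[1] & cnt <= iv[2]))
  expect_equal(sum(cnt), 10000 * 5)
})

test_that("counter updates follow the success/failure bookkeeping", {
  perf <- tibble::tibble(gene_id = c("a", "b", "c"),
                         T = c(4L, 0L, 2L), S = c(1L, 0L, 0L),
                         R = c(0.25, 0, 0), rank = c(1L, 2L, 3L))
  succ <- structure(list(status = "success", e = 0.1,
                         sampled_genes = c(1L, 3L), retained_genes = 1L),
                    class = "ppea_outcome")
  up <- update_performance(perf, succ, mode = "retained_only")
  expect_equal(up$T, c(5L, 0L, 3L))
  expect_equal(up$S, c(2L, 0L, 0L))
  expect_equal(up$R, c(0.4, 0, 0))

  fail <- structure(list(status = "failure_no_model", e = NA_real_,
                         sampled_genes = 2L, retained_genes = integer(0)),
                    class = "ppea_outcome")
  up2 <- update_performance(up, fail)
  expect_equal(up2$T[2], 1L); expect_equal(up2$S[2], 0L)
  expect_equal(up2$R[2], 0)

  # all_sampled credits every drawn gene
  up3 <- update_performance(perf, succ, mode = "all_sampled")
  expect_equal(up3$S, c(2L, 0L, 1L))
})

test_that("performance counters replay exactly from the outcome log", {
  sim <- small_sim(seed = 6)
  for (mode in c("retained_only", "all_sampled")) {
    cfg <- ppea_config(genes_per_iter = 6, max_iters = 300,
                       checkpoint_every = 100, seed = 6,
                       s_update_mode = mode)
    fit <- run_ppea(sim$matrix, cfg)
    Tn <- integer(60); Sn <- integer(60)
    for (k in seq_len(nrow(fit$log))) {
      s <- fit$log$sampled[[k]]
      Tn[s] <- Tn[s] + 1L
      if (fit$log$status[k] == "success") {
        credit <- if (mode == "retained_only") fit$log$retained[[k]] else s
        Sn[credit] <- Sn[credit] + 1L
      }
    }
    expect_identical(fit$performance$T, Tn)
    expect_identical(fit$performance$S, Sn)
    expect_equal(fit$performance$R, ifelse(Tn > 0, Sn / Tn, 0))
    # retained genes always among sampled; successes have e < alpha
    ok <- vapply(seq_len(nrow(fit$log)), function(k) {
      all(fit$log$retained[[k]] %in% fit$log$sampled[[k]])
    }, logical(1))
    expect_true(all(ok))
    succ <- fit$log$status == "success"
    expect_true(all(fit$log$test_error[succ] < cfg$alpha))
    tested_fail <- fit$log$status == "failure_tested"
    expect_true(all(fit$log$test_error[tested_fail] >= cfg$alpha))
  }
})

test_that("gene ranking sorts by power, then sampling count, then order", {
  expect_equal(rank_genes(c(0.9, 0.1, 0.5), c(10L, 10L, 10L)), c(1L, 3L, 2L))
  expect_equal(rank_genes(c(0.5, 0.5), c(100L, 10L)), c(1L, 2L))
  expect_equal(rank_genes(c(0.5, 0.5), c(10L, 100L)), c(2L, 1L))
  set.seed(9)
  for (rep in 1:5) {
    R <- sample(seq(0, 1, 0.05), 1000, replace = TRUE)
    Tn <- sample(0:20, 1000, replace = TRUE)
    expect_identical(rank_genes(R, Tn), oracle_rank(R, Tn))
  }
})

test_that("rank stability reproduces the closed-form Spearman values", {
  expect_equal(rank_stability(1:10, 1:10), 1)
  expect_equal(rank_stability(1:10, 10:1), -1)
  expect_equal(rank_stability(c(1, 2, 3, 4), c(2, 1, 3, 4)), 0.8)
  set.seed(10)
  for (rep in 1:10) {
    a <- sample(50); b <- sample(50)
    expect_equal(rank_stability(a, b), oracle_spearman(a, b))
  }
  expect_error(rank_stability(1:4, 1:5), "length")
})

test_that("sampling is conserved: sum(T) = k * p, S <= T, R in [0,1]", {
  set.seed(13)
  for (rep in 1:3) {
    p <- sample(3:8, 1)
    K <- sample(50:150, 1)
    sim <- small_sim(seed = rep, P = 40, q = 4)
    cfg <- ppea_config(genes_per_iter = p, max_iters = K,
                       checkpoint_every = 50, seed = rep)
    fit <- run_ppea(sim$matrix, cfg, keep_log = FALSE)
    expect_equal(sum(fit$performance$T), K * p)
    expect_true(all(fit$performance$S <= fit$performance$T))
    expect_true(all(fit$performance$R >= 0 & fit$performance$R <= 1))
    expect_setequal(fit$performance$rank, seq_len(40))
  }
})

test_that("with the classifier stubbed out every gene gets a uniform chance", {
  sim <- simulate_two_class(P = 200, n_pos = 12, n_neg = 12, q = 0, seed = 5)
  cfg <- ppea_config(genes_per_iter = 10, max_iters = 50000,
                     checkpoint_every = 50000, seed = 3,
                     classifier = "always_fail")
  fit <- run_ppea(sim$matrix, cfg, keep_log = FALSE)
  expect_equal(sum(fit$performance$T), 50000 * 10)
  expect_equal(mean(fit$performance$T), 50000 * 10 / 200)
  expect_gt(chisq.test(fit$performance$T)$p.value, 0.001)
  expect_equal(fit$n_failure_no_model, 50000L)
  expect_true(all(fit$performance$S == 0L))
})

test_that("a zero-iteration run leaves everything empty", {
  sim <- small_sim(seed = 14)
  cfg <- ppea_config(genes_per_iter = 5, max_iters = 0,
                     checkpoint_every = 10, seed = 14)
  fit <- run_ppea(sim$matrix, cfg)
  expect_true(all(fit$performance$T == 0L))
  expect_length(fit$checkpoints, 0)
  expect_false(fit$stopped)
  expect_equal(nrow(fit$log), 0)
})

test_that("pure noise under an unattainable error bound never succeeds", {
  sim <- small_sim(seed = 15, P = 30, q = 0)
  cfg <- ppea_config(alpha = 0, genes_per_iter = 5, max_iters = 60,
                     checkpoint_every = 30, seed = 15)
  fit <- run_ppea(sim$matrix, cfg)
  expect_equal(fit$n_success, 0L)
  expect_true(all(fit$performance$S == 0L))
})

test_that("two runs with the same seed are identical; different seeds differ", {
  sim <- small_sim(seed = 16)
  cfg <- ppea_config(genes_per_iter = 6, max_iters = 150,
                     checkpoint_every = 50, seed = 77)
  f1 <- run_ppea(sim$matrix, cfg)
  f2 <- run_ppea(sim$matrix, cfg)
  expect_identical(f1$performance, f2$performance)
  expect_identical(f1$log, f2$log)
  expect_identical(f1$rho_history, f2$rho_history)
  f3 <- run_ppea(sim$matrix, ppea_config(genes_per_iter = 6, max_iters = 150,
                                         checkpoint_every = 50, seed = 78))
  expect_false(identical(f1$performance, f3$performance))
})

test_that("checkpoint/resume equals the uninterrupted run bit for bit", {
  sim <- small_sim(seed = 18)
  make_cfg <- function(K) ppea_config(genes_per_iter = 6, max_iters = K,
                                      checkpoint_every = 40, seed = 5)
  full <- run_ppea(sim$matrix, make_cfg(120), keep_log = FALSE)
  for (split in c(40, 67)) {   # at a checkpoint boundary and mid-interval
    part <- run_ppea(sim$matrix, make_cfg(split), keep_log = FALSE)
    stem <- withr::local_tempfile()
    save_checkpoint(part, stem)
    resumed <- run_ppea(sim$matrix, make_cfg(120),
                        state = load_checkpoint(stem), keep_log = FALSE)
    expect_identical(resumed$performance, full$performance)
    expect_identical(resumed$rng_state, full$rng_state)
    expect_identical(resumed$rho_history, full$rho_history)
    expect_identical(resumed$checkpoints, full$checkpoints)
  }
})

test_that("rank stabilization stops the loop once rho reaches the threshold", {
  sim <- small_sim(seed = 19, P = 30, q = 6)
  cfg <- ppea_config(genes_per_iter = 5, max_iters = 5000,
                     checkpoint_every = 100, rho_stop = 0.95, seed = 19)
  fit <- run_ppea(sim$matrix, cfg, keep_log = FALSE)
  if (fit$stopped) {
    expect_lt(fit$iteration, 5000)
    expect_gte(utils::tail(fit$rho_history, 1), 0.95)
    expect_equal(fit$iteration %% 100, 0)
  }
  expect_true(all(fit$rho_history >= -1 & fit$rho_history <= 1))
})
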