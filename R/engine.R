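# The main loop: each iteration draws a small random gene subset plus a
# stratified train/test sample split, fits a shrunken-centroid model with a
# cross-validated threshold, and credits genes taking part in models that
# pass the hold-out error bound. Per-gene counters T (times sampled) and
# S (times credited) estimate predictive power R = S/T.

#' Draw one two-way bootstrap sample
#'
#' Draws `genes_per_iter` genes uniformly (without replacement by default)
#' and, within each class, a uniform train subset of `floor(beta * class
#' size)` samples; the remaining samples of each class form the disjoint
#' test set.
#'
#' @param x A [ppea_matrix()].
#' @param config A [ppea_config()].
#' @return A list of class `ppea_bootstrap` with integer index vectors
#'   `gene_indices`, `train_pos`, `train_neg`, `test_pos`, `test_neg`.
#' @export
draw_bootstrap <- function(x, config) {
  validate_config(config, x)
  lab <- labels_of(x)
  pos <- which(lab == positive_class(x))
  neg <- which(lab != positive_class(x))
  m1 <- floor(config$beta * length(pos))
  m2 <- floor(config$beta * length(neg))
  genes <- sample.int(nrow(x), config$genes_per_iter,
                      replace = isTRUE(config$gene_replace))
  tp <- pos[sample.int(length(pos), m1)]
  tn <- neg[sample.int(length(neg), m2)]
  structure(list(gene_indices = genes,
                 train_pos = tp, train_neg = tn,
                 test_pos = setdiff(pos, tp), test_neg = setdiff(neg, tn)),
            class = "ppea_bootstrap")
}

# One iteration against raw matrix internals (hot path).
.iterate_raw <- function(vals, lab, classes, pos, neg, config) {
  m1 <- floor(config$beta * length(pos))
  m2 <- floor(config$beta * length(neg))
  genes <- sample.int(nrow(vals), config$genes_per_iter,
                      replace = isTRUE(config$gene_replace))
  tp <- pos[sample.int(length(pos), m1)]
  tn <- neg[sample.int(length(neg), m2)]

  if (config$classifier == "always_fail") {
    return(list(status = "failure_no_model", e = NA_real_,
                sampled_genes = genes, retained_genes = integer(0),
                chosen_delta = NA_real_, chosen_error = NA_real_))
  }

  tr <- c(tp, tn)
  xtr <- vals[genes, tr, drop = FALSE]
  cv <- .cv_raw(xtr, lab[tr], classes, config$cv_folds,
                config$n_thresholds, config$priors)
  if (cv$chosen_error > config$alpha) {
    return(list(status = "failure_no_model", e = NA_real_,
                sampled_genes = genes, retained_genes = integer(0),
                chosen_delta = cv$chosen_delta,
                chosen_error = cv$chosen_error))
  }
  model <- .model_from_stats(cv$full_stats, cv$chosen_delta, config$priors,
                             as.character(genes))
  te <- c(setdiff(pos, tp), setdiff(neg, tn))
  sc <- .nsc_scores(model, vals[genes, te, drop = FALSE])
  pred_first <- sc[, 1] <= sc[, 2]
  e <- mean(pred_first != (lab[te] == classes[[1]]))
  success <- e < config$alpha
  retained <- genes[rowSums(model$shrunken_offsets != 0) > 0]
  list(status = if (success) "success" else "failure_tested", e = e,
       sampled_genes = genes, retained_genes = retained,
       chosen_delta = cv$chosen_delta, chosen_error = cv$chosen_error)
}

# CV over a raw matrix; mirrors select_threshold_cv() but skips container
# validation and keeps the full-train statistics for the final refit.
.cv_raw <- function(x, lab, classes, folds, n_thresholds, priors) {
  nk <- c(sum(lab == classes[[1]]), sum(lab == classes[[2]]))
  folds_eff <- min(folds, nk)
  full <- .nsc_stats(x, lab, classes)
  grid <- seq(0, max(abs(full$d)), length.out = n_thresholds)
  retained <- vapply(grid, function(dl) sum(rowSums(abs(full$d) > dl) > 0),
                     integer(1))
  fold <- .stratified_folds(lab, classes, folds_eff)
  err <- matrix(NA_real_, folds_eff, length(grid))
  for (f in seq_len(folds_eff)) {
    hold <- fold == f
    st <- .nsc_stats(x[, !hold, drop = FALSE], lab[!hold], classes)
    err[f, ] <- .cv_fold_errors(st, priors, x[, hold, drop = FALSE],
                                lab[hold], grid) / sum(hold)
  }
  cv_error <- colMeans(err)
  best <- min(cv_error)
  cand <- which(cv_error == best)
  cand <- cand[retained[cand] == min(retained[cand])]
  chosen <- cand[[length(cand)]]
  list(grid = grid, cv_error = cv_error, genes_retained = retained,
       chosen_delta = grid[[chosen]], chosen_error = best,
       full_stats = full)
}

#' Run a single bootstrap/model/test iteration
#'
#' Draws a bootstrap sample, selects the shrinkage threshold by
#' cross-validation on the training submatrix, and — unless no threshold
#' reaches the acceptable CV error (`failure_no_model`, hold-out test
#' skipped) — fits at the chosen threshold and scores the disjoint test
#' samples. The iteration is a `success` when the test error is strictly
#' below `alpha`.
#'
#' @inheritParams draw_bootstrap
#' @return A list of class `ppea_outcome`: `status` (one of `success`,
#'   `failure_tested`, `failure_no_model`), test error `e`, integer
#'   `sampled_genes` and `retained_genes` (indices into `x`), and the chosen
#'   threshold / CV error.
#' @export
run_iteration <- function(x, config) {
  validate_config(config, x)
  lab <- labels_of(x)
  classes <- c(positive_class(x), negative_class(x))
  pos <- which(lab == classes[[1]])
  neg <- which(lab != classes[[1]])
  out <- .iterate_raw(unclass(x), lab, classes, pos, neg, config)
  structure(out, class = "ppea_outcome")
}

#' Update the per-gene performance table with one iteration's outcome
#'
#' `T` is incremented for every sampled gene regardless of status; `S` is
#' incremented only on success, for the credited gene set (`retained_only`:
#' genes surviving shrinkage; `all_sampled`: every drawn gene). `R` is
#' recomputed as `S/T` (0 where `T = 0`) and ranks are refreshed.
#'
#' @param perf Performance tibble (`gene_id, T, S, R, rank`).
#' @param outcome A `ppea_outcome` from [run_iteration()].
#' @param mode Crediting mode, see [ppea_config()].
#' @return The updated tibble.
#' @export
update_performance <- function(perf, outcome,
                               mode = c("retained_only", "all_sampled")) {
  mode <- match.arg(mode)
  perf$T[outcome$sampled_genes] <- perf$T[outcome$sampled_genes] + 1L
  if (identical(outcome$status, "success")) {
    credit <- if (mode == "retained_only") outcome$retained_genes
              else outcome$sampled_genes
    perf$S[credit] <- perf$S[credit] + 1L
  }
  perf$R <- ifelse(perf$T > 0, perf$S / perf$T, 0)
  perf$rank <- rank_genes(perf)
  perf
}

#' Rank genes by estimated predictive power
#'
#' Orders by decreasing `R`; ties broken by larger `T`, then by input
#' order. Rank 1 is the most predictive gene.
#'
#' @param perf Performance tibble, or a numeric `R` vector (then supply `T`
#'   via `times_sampled`).
#' @param times_sampled Optional `T` vector when `perf` is a plain vector.
#' @return Integer rank vector, a permutation of `1..P` aligned with the
#'   input gene order.
#' @export
rank_genes <- function(perf, times_sampled = NULL) {
  if (is.data.frame(perf)) {
    R <- perf$R; Tn <- perf$T
  } else {
    R <- perf; Tn <- times_sampled %||% rep(0L, length(R))
  }
  ord <- order(-R, -Tn, seq_along(R))
  rk <- integer(length(R))
  rk[ord] <- seq_along(R)
  rk
}

#' Spearman correlation between two rank vectors
#'
#' Used as the stop criterion: the rank order is snapshotted periodically
#' and the run stops once consecutive snapshots agree closely. Computed with
#' the tie-aware (midrank) Spearman formula; for all-distinct ranks this
#' equals `1 - 6 * sum(d^2) / (P (P^2 - 1))`.
#'
#' @param prev_rank,cur_rank Equal-length numeric vectors (length >= 2).
#' @return Spearman rho in `[-1, 1]`.
#' @export
rank_stability <- function(prev_rank, cur_rank) {
  if (length(prev_rank) != length(cur_rank)) {
    abort("rank vectors differ in length.")
  }
  if (length(prev_rank) < 2) abort("need at least 2 ranks.")
  cor(prev_rank, cur_rank, method = "spearman")
}

#' Run the full predictive-power estimation loop
#'
#' Executes up to `max_iters` iterations of [run_iteration()], maintaining
#' the per-gene counters. Every `checkpoint_every` iterations the predictive
#' powers are snapshotted and the tie-aware Spearman correlation with the
#' previous snapshot is recorded; the run stops early once it reaches
#' `rho_stop`. The whole run — gene draws, sample splits, CV folds — is
#' reproducible from `config$seed`, and a run resumed from a checkpoint is
#' bit-identical to an uninterrupted one.
#'
#' @param x A [ppea_matrix()].
#' @param config A [ppea_config()]; defaults to the config stored in
#'   `state` when resuming.
#' @param state A `ppea_state` from [load_checkpoint()] (or a previous
#'   `ppea_fit`) to resume from.
#' @param keep_log Keep the per-iteration outcome log (status, test error,
#'   sampled/retained gene indices) in the result.
#' @return An object of class `ppea_fit`: `performance` (tibble
#'   `gene_id, T, S, R, rank`), iteration counts by status, the checkpoint
#'   iterations with their `rho_history` and rank `snapshots`, `stopped`,
#'   the saved RNG state, and (optionally) the outcome `log` tibble.
#' @export
#' @examples
#' sim <- simulate_two_class(P = 40, n_pos = 8, n_neg = 8, q = 4,
#'                           effect = 3, seed = 1)
#' cfg <- ppea_config(genes_per_iter = 5, max_iters = 50,
#'                    checkpoint_every = 25, seed = 1)
#' fit <- run_ppea(sim$matrix, cfg)
#' head(dplyr::arrange(fit$performance, rank))
run_ppea <- function(x, config = NULL, state = NULL, keep_log = TRUE) {
  stopifnot(inherits(x, "ppea_matrix"))
  if (is.null(config)) {
    if (is.null(state)) abort("supply `config` (or a `state` that holds one).")
    config <- state$config
  }
  validate_config(config, x)
  P <- nrow(x)
  lab <- labels_of(x)
  classes <- c(positive_class(x), negative_class(x))
  pos <- which(lab == classes[[1]])
  neg <- which(lab != classes[[1]])
  vals <- unclass(x)

  if (is.null(state)) {
    set.seed(config$seed)
    Tn <- integer(P); Sn <- integer(P)
    k0 <- 0L
    n_succ <- 0L; n_ft <- 0L; n_fnm <- 0L
    checkpoints <- integer(0); rho_history <- numeric(0)
    last_snapshot <- NULL
    stopped <- FALSE
  } else {
    if (!identical(state$performance$gene_id, rownames(x))) {
      abort("checkpoint gene ids do not match `x`.")
    }
    assign(".Random.seed", as.integer(state$rng_state), envir = globalenv())
    Tn <- state$performance$T; Sn <- state$performance$S
    k0 <- state$iteration
    n_succ <- state$n_success; n_ft <- state$n_failure_tested
    n_fnm <- state$n_failure_no_model
    checkpoints <- state$checkpoints; rho_history <- state$rho_history
    last_snapshot <- state$last_snapshot
    stopped <- isTRUE(state$stopped)
  }

  K <- config$max_iters
  n_new <- max(0L, K - k0)
  log_status <- if (keep_log) character(n_new)
  log_e <- if (keep_log) numeric(n_new)
  log_sampled <- if (keep_log) vector("list", n_new)
  log_retained <- if (keep_log) vector("list", n_new)
  snapshots <- list()
  i_log <- 0L
  k <- k0

  while (k < K && !stopped) {
    k <- k + 1L
    out <- .iterate_raw(vals, lab, classes, pos, neg, config)
    Tn[out$sampled_genes] <- Tn[out$sampled_genes] + 1L
    if (out$status == "success") {
      n_succ <- n_succ + 1L
      credit <- if (config$s_update_mode == "retained_only")
        out$retained_genes else out$sampled_genes
      Sn[credit] <- Sn[credit] + 1L
    } else if (out$status == "failure_tested") {
      n_ft <- n_ft + 1L
    } else {
      n_fnm <- n_fnm + 1L
    }
    if (keep_log) {
      i_log <- i_log + 1L
      log_status[i_log] <- out$status
      log_e[i_log] <- out$e
      log_sampled[[i_log]] <- out$sampled_genes
      log_retained[[i_log]] <- out$retained_genes
    }
    if (k %% config$checkpoint_every == 0L) {
      R <- ifelse(Tn > 0L, Sn / Tn, 0)
      snap <- rank_genes(R, Tn)
      checkpoints <- c(checkpoints, k)
      snapshots[[length(snapshots) + 1L]] <- snap
      if (!is.null(last_snapshot)) {
        rho <- rank_stability(last_snapshot, snap)
        rho_history <- c(rho_history, rho)
        if (is.finite(rho) && rho >= config$rho_stop) stopped <- TRUE
      }
      last_snapshot <- snap
    }
  }

  R <- ifelse(Tn > 0L, Sn / Tn, 0)
  perf <- tibble(gene_id = rownames(x), T = Tn, S = Sn, R = R,
                 rank = rank_genes(R, Tn))
  log <- NULL
  if (keep_log) {
    log <- tibble(iteration = seq_len(i_log) + k0,
                  status = log_status[seq_len(i_log)],
                  test_error = log_e[seq_len(i_log)],
                  sampled = log_sampled[seq_len(i_log)],
                  retained = log_retained[seq_len(i_log)])
  }
  structure(list(
    performance = perf, iteration = k, config = config,
    n_success = n_succ, n_failure_tested = n_ft, n_failure_no_model = n_fnm,
    checkpoints = checkpoints, rho_history = rho_history,
    snapshots = snapshots, last_snapshot = last_snapshot,
    stopped = stopped,
    rng_kind = paste(RNGkind(), collapse = " "),
    rng_state = get(".Random.seed", envir = globalenv()),
    log = log),
    class = "ppea_fit")
}

#' @export
print.ppea_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "<ppea_fit> %d genes, %d iterations (%d success / %d tested-fail / ",
    "%d no-model)\n  stopped: %s; last rho: %s\n"),
    nrow(x$performance), x$iteration, x$n_success, x$n_failure_tested,
    x$n_failure_no_model, x$stopped,
    if (length(x$rho_history)) sprintf("%.5f", utils::tail(x$rho_history, 1))
    else "NA"))
  invisible(x)
}

#' Broom-style accessors for fitted objects
#'
#' `tidy()` returns the per-element table of a result (per-gene counters for
#' a `ppea_fit`, the threshold grid for an `nsc_cv`, per-gene centroids for
#' an `nsc_model`, the gene list for a `ppea_signature`); `glance()` returns
#' a one-row summary.
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy ppea_fit
#' @export
tidy.ppea_fit <- function(x, ...) {
  dplyr::arrange(x$performance, .data$rank)
}

#' @rdname tidiers
#' @method glance ppea_fit
#' @export
glance.ppea_fit <- function(x, ...) {
  tibble(iterations = x$iteration,
         n_success = x$n_success,
         n_failure_tested = x$n_failure_tested,
         n_failure_no_model = x$n_failure_no_model,
         success_rate = if (x$iteration > 0) x$n_success / x$iteration else NA_real_,
         n_checkpoints = length(x$checkpoints),
         last_rho = if (length(x$rho_history)) utils::tail(x$rho_history, 1) else NA_real_,
         stopped = x$stopped)
}

#' Plot methods for a fitted run
#'
#' `autoplot()` shows estimated predictive power against rank;
#' `plot_rank_stability()` shows the consecutive-checkpoint Spearman trace
#' that drives the stop criterion.
#'
#' @param object,fit A `ppea_fit`.
#' @param top_n Highlight the top-n ranked genes.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ppea_fit
#' @export
autoplot.ppea_fit <- function(object, top_n = 20, ...) {
  df <- dplyr::arrange(object$performance, .data$rank)
  df$top <- df$rank <= top_n
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$R,
                                   colour = .data$top)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "red", `FALSE` = "grey30")) +
    ggplot2::labs(x = "rank (1 = most predictive)",
                  y = "estimated predictive power R = S/T") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ppea_fit
#' @export
plot_rank_stability <- function(fit, ...) {
  stopifnot(inherits(fit, "ppea_fit"))
  if (length(fit$rho_history) == 0) {
    abort("no checkpoint history to plot (fewer than 2 checkpoints).")
  }
  df <- tibble(iteration = fit$checkpoints[-1], rho = fit$rho_history)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$rho)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = fit$config$rho_stop,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "iteration",
                  y = "Spearman rho vs previous checkpoint") +
    ggplot2::theme_minimal()
}
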