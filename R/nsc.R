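# Nearest shrunken centroid (PAM) classifier: per-gene class centroids are
# standardised against the pooled within-class SD and soft-thresholded by
# delta; genes whose standardised differences vanish drop out of the model.

# Sufficient statistics shared by fitting and cross-validation.
# x: genes x samples, lab: per-sample labels, classes: c(first, second) --
# the first class is the deterministic tie-break winner.
.nsc_stats <- function(x, lab, classes) {
  n <- length(lab)
  idx1 <- which(lab == classes[[1]])
  idx2 <- which(lab == classes[[2]])
  nk <- c(length(idx1), length(idx2))
  if (any(nk == 0)) abort("a class has zero training samples.")
  cent <- cbind(rowMeans(x[, idx1, drop = FALSE]),
                rowMeans(x[, idx2, drop = FALSE]))
  overall <- (cent[, 1] * nk[1] + cent[, 2] * nk[2]) / n
  ss <- rowSums((x[, idx1, drop = FALSE] - cent[, 1])^2) +
    rowSums((x[, idx2, drop = FALSE] - cent[, 2])^2)
  s <- if (n > 2) sqrt(ss / (n - 2)) else rep(0, nrow(x))
  s0 <- median(s)
  if (all(s + s0 == 0)) abort("all genes have zero within-class variance.")
  mk <- sqrt(1 / nk - 1 / n)
  d <- (cent - overall) / ((s + s0) * rep(mk, each = nrow(x)))
  list(classes = classes, n = n, nk = nk, cent = cent, overall = overall,
       s = s, s0 = s0, mk = mk, d = d)
}

.soft <- function(d, delta) sign(d) * pmax(abs(d) - delta, 0)

.nsc_priors <- function(stats, priors) {
  if (priors == "uniform") c(0.5, 0.5) else stats$nk / stats$n
}

.model_from_stats <- function(stats, delta, priors, gene_ids) {
  dprime <- .soft(stats$d, delta)
  shrunk <- stats$overall +
    dprime * (stats$s + stats$s0) * rep(stats$mk, each = length(stats$s))
  structure(list(
    class_names = stats$classes,
    gene_ids = gene_ids,
    overall_centroid = setNames(stats$overall, gene_ids),
    class_centroids = `dimnames<-`(stats$cent, list(gene_ids, stats$classes)),
    shrunken_offsets = `dimnames<-`(dprime, list(gene_ids, stats$classes)),
    shrunken_centroids = `dimnames<-`(shrunk, list(gene_ids, stats$classes)),
    pooled_sd = setNames(stats$s, gene_ids),
    sd_floor = stats$s0,
    mk = stats$mk,
    delta = delta,
    priors = setNames(.nsc_priors(stats, priors), stats$classes),
    retained_genes = gene_ids[rowSums(dprime != 0) > 0]),
    class = "nsc_model")
}

#' Fit a nearest shrunken centroid model
#'
#' Standardised centroid differences
#' `d_ik = (class centroid - overall centroid) / (m_k (s_i + s0))` with
#' `m_k = sqrt(1/n_k - 1/n)` are soft-thresholded at `delta`
#' (`d'_ik = sign(d_ik) max(|d_ik| - delta, 0)`); shrunken class centroids
#' are rebuilt as `overall + m_k (s_i + s0) d'_ik`. `s_i` is the pooled
#' within-class standard deviation and `s0` its median across genes.
#'
#' @param train A [ppea_matrix()] (genes x samples with two-class labels).
#' @param delta Non-negative shrinkage threshold.
#' @param priors `"class"` (training frequencies) or `"uniform"`.
#' @return An object of class `nsc_model`. The positive class is listed
#'   first in `class_names` and wins exact score ties in prediction.
#' @export
#' @examples
#' sim <- simulate_two_class(P = 30, n_pos = 10, n_neg = 10, q = 4,
#'                           effect = 3, seed = 1)
#' fit <- fit_nsc(sim$matrix, delta = 1)
#' length(fit$retained_genes)
fit_nsc <- function(train, delta = 0, priors = c("class", "uniform")) {
  priors <- match.arg(priors)
  stopifnot(inherits(train, "ppea_matrix"), delta >= 0)
  classes <- c(positive_class(train), negative_class(train))
  stats <- .nsc_stats(unclass(train), labels_of(train), classes)
  .model_from_stats(stats, delta, priors, rownames(train))
}

#' @export
print.nsc_model <- function(x, ...) {
  cat(sprintf("<nsc_model> %d genes (%d retained at delta = %.4g), classes: %s\n",
              length(x$gene_ids), length(x$retained_genes), x$delta,
              paste(x$class_names, collapse = " vs ")))
  invisible(x)
}

# Discriminant scores for a genes x samples matrix against a fitted model;
# returns samples x 2 matrix of scores (smaller = closer).
.nsc_scores <- function(model, x) {
  denom <- model$pooled_sd + model$sd_floor
  sc <- vapply(1:2, function(k) {
    colSums(((x - model$shrunken_centroids[, k]) / denom)^2) -
      2 * log(model$priors[[k]])
  }, numeric(ncol(x)))
  if (is.null(dim(sc))) sc <- matrix(sc, nrow = 1)
  colnames(sc) <- model$class_names
  sc
}

.align_genes <- function(model, samples) {
  x <- if (inherits(samples, "ppea_matrix")) unclass(samples) else samples
  if (!is.null(rownames(x))) {
    if (!all(model$gene_ids %in% rownames(x))) {
      abort("`samples` is missing genes required by the model.")
    }
    x <- x[model$gene_ids, , drop = FALSE]
  } else if (nrow(x) != length(model$gene_ids)) {
    abort("`samples` rows do not align with the model's genes.")
  }
  x
}

#' Classify samples with a fitted shrunken-centroid model
#'
#' Each sample is assigned to the class whose shrunken centroid is nearest
#' in the standardised squared-distance discriminant
#' `sum_i (x_i - centroid_ik)^2 / (s_i + s0)^2 - 2 log(prior_k)`; exact ties
#' go to the first class name.
#'
#' @param model An `nsc_model`.
#' @param samples Expression matrix covering the model's genes (rows matched
#'   by rowname when present, by position otherwise).
#' @return Tibble with one row per sample: `sample_id`, predicted `pred`,
#'   and one discriminant-score column per class (`score_*`).
#' @export
predict_nsc <- function(model, samples) {
  x <- .align_genes(model, samples)
  sc <- .nsc_scores(model, x)
  pred <- model$class_names[max.col(-sc, ties.method = "first")]
  out <- tibble(
    sample_id = colnames(x) %||% as.character(seq_len(ncol(x))),
    pred = pred)
  out[[paste0("score_", model$class_names[[1]])]] <- sc[, 1]
  out[[paste0("score_", model$class_names[[2]])]] <- sc[, 2]
  out
}

#' Hold-out error rate of a fitted model
#'
#' @param model An `nsc_model`.
#' @param test A [ppea_matrix()] of held-out samples.
#' @return Misclassified fraction in `[0, 1]`.
#' @export
test_error <- function(model, test) {
  pred <- predict_nsc(model, test)$pred
  mean(pred != labels_of(test))
}

# Per-fold misclassification counts over a whole delta grid, vectorised:
# for test sample z = (x - overall)/(s+s0), the class-k score at delta is
# sum(z^2) - 2 m_k z.D_k(delta) + m_k^2 sum(D_k(delta)^2) - 2 log prior_k.
.cv_fold_errors <- function(stats, priors, x_test, lab_test, grid) {
  denom <- stats$s + stats$s0
  z <- (x_test - stats$overall) / denom          # genes x ntest
  zz <- colSums(z^2)
  pr <- .nsc_priors(stats, priors)
  G <- length(grid)
  score <- array(0, dim = c(length(zz), G, 2))
  for (k in 1:2) {
    Dk <- .soft(matrix(stats$d[, k], nrow(stats$d), G),
                matrix(grid, nrow(stats$d), G, byrow = TRUE))
    cross <- crossprod(z, Dk)                    # ntest x G
    score[, , k] <- zz - 2 * stats$mk[k] * cross +
      rep(stats$mk[k]^2 * colSums(Dk^2), each = length(zz)) -
      2 * log(pr[k])
  }
  # ties go to the first class
  pred_first <- score[, , 1] <= score[, , 2]
  truth_first <- matrix(lab_test == stats$classes[[1]], length(lab_test), G)
  colSums(pred_first != truth_first)
}

# Stratified fold assignment: permutes each class and deals folds round-robin.
.stratified_folds <- function(lab, classes, folds) {
  fold <- integer(length(lab))
  for (cl in classes) {
    idx <- which(lab == cl)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold
}

#' Choose the shrinkage threshold by stratified cross-validation
#'
#' Evaluates an equally spaced grid of `n_thresholds` delta values from 0 to
#' the largest absolute standardised centroid difference of the full
#' training set, scoring each by mean misclassification rate over stratified
#' folds. The winner is the delta with the lowest cross-validated error;
#' among ties, the one retaining the fewest genes, then the largest delta.
#'
#' @param train A [ppea_matrix()].
#' @param folds Requested fold count (reduced to the smaller class size when
#'   necessary, with a message).
#' @param n_thresholds Grid size.
#' @param priors See [fit_nsc()].
#' @param quiet Suppress the fold-reduction message.
#' @return An object of class `nsc_cv` with the grid, per-delta CV error and
#'   retained-gene count, and the chosen delta / error.
#' @export
select_threshold_cv <- function(train, folds = 10, n_thresholds = 30,
                                priors = c("class", "uniform"),
                                quiet = FALSE) {
  priors <- match.arg(priors)
  stopifnot(inherits(train, "ppea_matrix"))
  x <- unclass(train)
  lab <- labels_of(train)
  classes <- c(positive_class(train), negative_class(train))
  nk <- c(sum(lab == classes[[1]]), sum(lab == classes[[2]]))
  folds_eff <- min(folds, nk)
  if (folds_eff < folds && !quiet) {
    inform(sprintf("reducing folds from %d to %d (smaller class has %d samples)",
                   folds, folds_eff, min(nk)))
  }
  if (folds_eff < 2) abort("need at least 2 samples per class for CV.")

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
  chosen <- cand[[length(cand)]]        # largest delta among remaining ties
  structure(list(grid = grid, cv_error = cv_error, genes_retained = retained,
                 chosen_delta = grid[[chosen]], chosen_error = best,
                 folds = folds_eff, classes = classes),
            class = "nsc_cv")
}

#' @export
print.nsc_cv <- function(x, ...) {
  cat(sprintf("<nsc_cv> %d-fold CV over %d thresholds: delta = %.4g, error = %.3f, %d genes\n",
              x$folds, length(x$grid), x$chosen_delta, x$chosen_error,
              x$genes_retained[[match(x$chosen_delta, x$grid)]]))
  invisible(x)
}

#' @rdname tidiers
#' @method tidy nsc_cv
#' @export
tidy.nsc_cv <- function(x, ...) {
  tibble(delta = x$grid, cv_error = x$cv_error,
         genes_retained = x$genes_retained)
}

#' @rdname tidiers
#' @method glance nsc_cv
#' @export
glance.nsc_cv <- function(x, ...) {
  tibble(chosen_delta = x$chosen_delta, chosen_error = x$chosen_error,
         folds = x$folds, n_thresholds = length(x$grid))
}

#' @rdname tidiers
#' @method tidy nsc_model
#' @export
tidy.nsc_model <- function(x, ...) {
  tibble(gene_id = rep(x$gene_ids, 2),
         class = rep(x$class_names, each = length(x$gene_ids)),
         centroid = c(x$class_centroids),
         shrunken_offset = c(x$shrunken_offsets),
         shrunken_centroid = c(x$shrunken_centroids)) |>
    dplyr::mutate(retained = .data$gene_id %in% x$retained_genes)
}

#' @rdname tidiers
#' @method glance nsc_model
#' @export
glance.nsc_model <- function(x, ...) {
  tibble(delta = x$delta, n_genes = length(x$gene_ids),
         n_retained = length(x$retained_genes), sd_floor = x$sd_floor)
}

#' Cross-validation error profile plot
#'
#' @param object An `nsc_cv` from [select_threshold_cv()].
#' @param ... Unused.
#' @return A ggplot of CV error against the shrinkage threshold, annotated
#'   with the retained-gene count and the chosen delta.
#' @method autoplot nsc_cv
#' @export
autoplot.nsc_cv <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta, y = .data$cv_error)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(size = .data$genes_retained),
                        alpha = 0.7) +
    ggplot2::geom_vline(xintercept = object$chosen_delta,
                        linetype = "dashed", colour = "red") +
    ggplot2::scale_size_continuous(name = "genes retained") +
    ggplot2::labs(x = "shrinkage threshold Δ",
                  y = "cross-validated error rate") +
    ggplot2::theme_minimal()
}
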