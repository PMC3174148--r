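# Minimal-signature construction: take the top-ranked genes, grow the set
# (10, 15, 20, ...) until a cross-validated shrunken-centroid model meets
# the acceptable error bound, and report confusion-matrix metrics.

.rank_vector <- function(rank, gene_ids) {
  if (inherits(rank, "ppea_fit")) rank <- rank$performance
  if (is.data.frame(rank)) {
    if (!all(c("gene_id", "rank") %in% names(rank))) {
      abort("`rank` table needs gene_id and rank columns.")
    }
    if (!all(gene_ids %in% rank$gene_id)) {
      abort("`rank` does not cover all genes in the matrix.")
    }
    return(rank$rank[match(gene_ids, rank$gene_id)])
  }
  if (length(rank) != length(gene_ids)) {
    abort("`rank` does not cover all genes in the matrix.")
  }
  as.integer(rank)
}

#' Build the minimal top-n predictive signature
#'
#' Starting from the `start_n` top-ranked genes, fits a shrunken-centroid
#' model on all samples with the shrinkage threshold chosen by stratified
#' cross-validation, and accepts the first gene-set size whose
#' cross-validated error is at most `max_error` (default 20%). If the bound
#' is not met the set grows by `step` genes, up to `max_n`.
#'
#' @param x A [ppea_matrix()] of all samples.
#' @param rank Gene ranking: a `ppea_fit`, a performance tibble, or an
#'   integer rank vector aligned with the rows of `x` (1 = most predictive).
#' @param start_n,step,max_n Gene-set growth schedule (defaults 10, 5, 20).
#' @param max_error Acceptable cross-validated error rate.
#' @param folds,n_thresholds,priors Passed to [select_threshold_cv()] /
#'   [fit_nsc()].
#' @return An object of class `ppea_signature`: ordered `gene_ids`, the
#'   fitted `model`, `n_used`, `cv_error`, and the `cv` grid object.
#'   Errors if no size up to `max_n` meets the bound, naming the best
#'   size/error found.
#' @export
#' @examples
#' sim <- simulate_two_class(P = 60, n_pos = 12, n_neg = 12, q = 8,
#'                           effect = 3, seed = 2)
#' rk <- rank_genes(rep(c(1, 0), c(8, 52)), rep(100L, 60))
#' sig <- build_signature(sim$matrix, rk, start_n = 10, max_n = 20)
#' glance(sig)
build_signature <- function(x, rank, start_n = 10, step = 5, max_n = 20,
                            max_error = 0.2, folds = 10, n_thresholds = 30,
                            priors = c("class", "uniform")) {
  priors <- match.arg(priors)
  stopifnot(inherits(x, "ppea_matrix"), start_n >= 1, step >= 1,
            max_n >= start_n, max_error >= 0, max_error <= 1)
  rk <- .rank_vector(rank, rownames(x))
  sizes <- unique(as.integer(pmin(seq(start_n, max_n, by = step), nrow(x))))
  best <- NULL
  for (n in sizes) {
    top <- order(rk)[seq_len(n)]
    sub <- subset_ppea(x, genes = top)
    cv <- select_threshold_cv(sub, folds = folds,
                              n_thresholds = n_thresholds, priors = priors,
                              quiet = TRUE)
    if (is.null(best) || cv$chosen_error < best$error) {
      best <- list(n = n, error = cv$chosen_error)
    }
    if (cv$chosen_error <= max_error) {
      model <- fit_nsc(sub, delta = cv$chosen_delta, priors = priors)
      return(structure(list(gene_ids = rownames(sub), model = model,
                            n_used = n, cv_error = cv$chosen_error,
                            cv = cv, max_error = max_error),
                       class = "ppea_signature"))
    }
  }
  abort(sprintf(
    "no signature of up to %d genes met CV error <= %.3g (best: %d genes at %.3g).",
    max_n, max_error, best$n, best$error))
}

#' @export
print.ppea_signature <- function(x, ...) {
  cat(sprintf("<ppea_signature> %d genes, CV error %.3f (delta = %.4g)\n",
              x$n_used, x$cv_error, x$model$delta))
  cat("  ", paste(head(x$gene_ids, 10), collapse = ", "),
      if (x$n_used > 10) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @rdname tidiers
#' @method tidy ppea_signature
#' @export
tidy.ppea_signature <- function(x, ...) {
  tibble(gene_id = x$gene_ids,
         signature_rank = seq_along(x$gene_ids),
         retained = x$gene_ids %in% x$model$retained_genes)
}

#' @rdname tidiers
#' @method glance ppea_signature
#' @export
glance.ppea_signature <- function(x, ...) {
  tibble(n_used = x$n_used, cv_error = x$cv_error, delta = x$model$delta,
         n_retained = length(x$model$retained_genes),
         max_error = x$max_error)
}

#' Confusion-matrix performance of a classifier on labeled samples
#'
#' Predicts the given samples and tabulates true/false positives and
#' negatives against their labels, reporting sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, positive and negative predictive values
#' `TP/(TP+FP)` and `TN/(TN+FN)`, and the error rate
#' `(FP+FN)/(TP+FN+FP+TN)`. Ratios with a zero denominator are returned as
#' `NaN` with a warning. Note that evaluating on the training samples is a
#' resubstitution estimate and overstates generalisation; use a held-out
#' matrix for honest numbers.
#'
#' @param object An `nsc_model` or `ppea_signature`.
#' @param test A [ppea_matrix()] of labeled samples to score.
#' @param positive Label counted as positive (defaults to the matrix's
#'   positive class).
#' @return One-row tibble: `TP, FN, FP, TN, sensitivity, specificity, ppv,
#'   npv, error_rate`.
#' @export
evaluate <- function(object, test, positive = NULL) {
  UseMethod("evaluate")
}

#' @rdname evaluate
#' @export
evaluate.ppea_signature <- function(object, test, positive = NULL) {
  evaluate(object$model, test, positive = positive)
}

#' @rdname evaluate
#' @export
evaluate.nsc_model <- function(object, test, positive = NULL) {
  stopifnot(inherits(test, "ppea_matrix"))
  positive <- positive %||% positive_class(test)
  truth <- labels_of(test)
  if (!positive %in% truth) abort("`positive` label absent from test set.")
  pred <- predict_nsc(object, test)$pred
  confusion_report(pred, truth, positive)
}

#' Confusion-matrix report from predicted and true labels
#'
#' @param pred,truth Equal-length label vectors.
#' @param positive Label counted as positive.
#' @return One-row tibble, see [evaluate()].
#' @export
confusion_report <- function(pred, truth, positive) {
  stopifnot(length(pred) == length(truth))
  tp <- sum(pred == positive & truth == positive)
  fn <- sum(pred != positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  tn <- sum(pred != positive & truth != positive)
  denoms <- c(tp + fn, tn + fp, tp + fp, tn + fn)
  if (any(denoms == 0)) {
    warn("a confusion-matrix denominator is zero; reporting NaN for that rate.")
  }
  tibble(TP = tp, FN = fn, FP = fp, TN = tn,
         sensitivity = tp / (tp + fn),
         specificity = tn / (tn + fp),
         ppv = tp / (tp + fp),
         npv = tn / (tn + fn),
         error_rate = (fp + fn) / (tp + fn + fp + tn))
}
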