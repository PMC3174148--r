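#' Labeled two-class expression matrix
#'
#' The central container: a numeric matrix of expression intensities with
#' genes in rows and samples in columns, plus a binary class label for every
#' sample. All downstream steps (filtering, bootstrap ranking, signature
#' building) consume this object.
#'
#' @param values Numeric matrix, genes in rows (rownames are gene ids),
#'   samples in columns (colnames are sample ids). All values must be finite.
#' @param labels Character vector of per-sample class labels, one per column
#'   of `values`, with exactly two distinct values; may be named by sample id.
#' @param positive Which label value denotes the positive (e.g. toxic) class.
#'   Defaults to `"positive"` when present, otherwise the first label in
#'   sorted order.
#'
#' @return An object of class `ppea_matrix`: the matrix with attributes
#'   `labels` (character) and `positive` (scalar character).
#' @export
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' x <- ppea_matrix(m, c("positive", "positive", "negative", "negative"))
#' n_samples(x)
ppea_matrix <- function(values, labels, positive = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (genes x samples).")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` needs rownames (gene ids) and colnames (sample ids).")
  }
  if (anyDuplicated(rownames(values))) abort("duplicate gene ids.")
  if (anyDuplicated(colnames(values))) abort("duplicate sample ids.")
  if (!all(is.finite(values))) abort("all expression values must be finite.")
  if (nrow(values) < 2) abort("need at least 2 genes.")
  labels <- setNames(as.character(labels), names(labels))
  if (!is.null(names(labels))) {
    missing <- setdiff(colnames(values), names(labels))
    if (length(missing)) {
      abort(paste0("no label for sample(s): ",
                   paste(head(missing, 5), collapse = ", ")))
    }
    labels <- labels[colnames(values)]
  }
  if (length(labels) != ncol(values)) {
    abort("`labels` must have one entry per sample.")
  }
  if (anyNA(labels)) abort("labels contain missing values.")
  classes <- sort(unique(labels))
  if (length(classes) != 2) {
    abort(paste0("exactly two classes required, found: ",
                 paste(classes, collapse = ", ")))
  }
  if (is.null(positive)) {
    positive <- if ("positive" %in% classes) "positive" else classes[[1]]
  }
  if (!positive %in% classes) abort("`positive` is not one of the labels.")
  if (min(table(labels)) < 2) abort("each class needs at least 2 samples.")
  structure(values,
            labels = unname(labels),
            positive = positive,
            class = c("ppea_matrix", "matrix", "array"))
}

#' Coerce a tidy gene-by-sample data frame to a `ppea_matrix`
#'
#' @param data Data frame whose first column holds gene ids and whose
#'   remaining columns are numeric, one per sample.
#' @param labels Per-sample labels; either a character vector (named by
#'   sample id or in column order) or a two-column data frame
#'   (sample id, label).
#' @inheritParams ppea_matrix
#' @return A [ppea_matrix()].
#' @export
as_ppea_matrix <- function(data, labels, positive = NULL) {
  stopifnot(is.data.frame(data), ncol(data) >= 3)
  ids <- as.character(data[[1]])
  vals <- as.matrix(data[, -1, drop = FALSE])
  if (!is.numeric(vals)) abort("expression columns must all be numeric.")
  rownames(vals) <- ids
  if (is.data.frame(labels)) {
    labels <- setNames(as.character(labels[[2]]), as.character(labels[[1]]))
  }
  ppea_matrix(vals, labels, positive = positive)
}

#' @export
print.ppea_matrix <- function(x, ...) {
  lab <- labels_of(x)
  cat(sprintf("<ppea_matrix> %d genes x %d samples (%d %s / %d other)\n",
              nrow(x), ncol(x), sum(lab == positive_class(x)),
              positive_class(x), sum(lab != positive_class(x))))
  invisible(x)
}

#' Accessors for `ppea_matrix` metadata
#'
#' @param x A [ppea_matrix()].
#' @return `labels_of()` the character label vector; `positive_class()` /
#'   `negative_class()` the class names; `n_samples()` a named count per
#'   class (positive first).
#' @export
labels_of <- function(x) attr(x, "labels")

#' @rdname labels_of
#' @export
positive_class <- function(x) attr(x, "positive")

#' @rdname labels_of
#' @export
negative_class <- function(x) {
  setdiff(unique(labels_of(x)), positive_class(x))
}

#' @rdname labels_of
#' @export
n_samples <- function(x) {
  lab <- labels_of(x)
  pos <- positive_class(x)
  c(positive = sum(lab == pos), negative = sum(lab != pos))
}

#' Subset helper keeping labels in sync
#'
#' @param x A [ppea_matrix()].
#' @param genes,samples Row / column indices (any form `[` accepts).
#' @return A [ppea_matrix()] restricted to the selection (labels follow the
#'   sample selection). Dropping below 2 samples per class is an error.
#' @export
subset_ppea <- function(x, genes = NULL, samples = NULL) {
  vals <- unclass(x)
  attr(vals, "labels") <- NULL
  attr(vals, "positive") <- NULL
  lab <- labels_of(x)
  if (!is.null(genes)) vals <- vals[genes, , drop = FALSE]
  if (!is.null(samples)) {
    vals <- vals[, samples, drop = FALSE]
    lab <- lab[if (is.character(samples)) match(samples, colnames(x)) else samples]
  }
  ppea_matrix(vals, lab, positive = positive_class(x))
}

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an expression matrix and its sample labels from delimited text
#'
#' Expression file: first column gene id, header row of sample ids, numeric
#' cells; tab-delimited unless the extension is `.csv`. Labels file: two
#' columns (sample id, class token), with or without a header.
#'
#' @param path Expression file.
#' @param labels_path Labels file.
#' @param positive Label token for the positive class (see [ppea_matrix()]).
#' @param transpose If `TRUE` the file is samples-in-rows and is transposed
#'   on read.
#' @return A [ppea_matrix()]; row and column order follow the file.
#' @export
read_expression <- function(path, labels_path, positive = NULL,
                            transpose = FALSE) {
  dat <- utils::read.delim(path, sep = delim_for(path), header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(dat) < 2) abort("expression file needs an id column plus data.")
  ids <- as.character(dat[[1]])
  vals <- as.matrix(dat[, -1, drop = FALSE])
  if (!is.numeric(vals)) abort("non-numeric cells in expression file.")
  rownames(vals) <- ids
  if (transpose) vals <- t(vals)

  lab <- utils::read.delim(labels_path, sep = delim_for(labels_path),
                           header = FALSE, stringsAsFactors = FALSE)
  # tolerate a header row: drop it if its first field is not a sample id
  if (nrow(lab) >= 1 && !(as.character(lab[1, 1]) %in% colnames(vals))) {
    lab <- lab[-1, , drop = FALSE]
  }
  if (ncol(lab) < 2) abort("labels file needs two columns: sample id, class.")
  labels <- setNames(as.character(lab[[2]]), as.character(lab[[1]]))
  ppea_matrix(vals, labels, positive = positive)
}

#' Write an expression matrix (and optionally its labels) to delimited text
#'
#' @param x A [ppea_matrix()] or plain matrix with dimnames.
#' @param path Output expression file (`.csv` for comma, else tab).
#' @param labels_path Optional output file for the sample labels.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, labels_path = NULL) {
  df <- data.frame(gene_id = rownames(x), unclass(x)[, , drop = FALSE],
                   check.names = FALSE)
  utils::write.table(df, path, sep = delim_for(path), quote = FALSE,
                     row.names = FALSE)
  if (!is.null(labels_path)) {
    if (is.null(labels_of(x))) abort("`x` carries no labels to write.")
    utils::write.table(
      data.frame(sample_id = colnames(x), label = labels_of(x)),
      labels_path, sep = delim_for(labels_path), quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Engine configuration
#'
#' Bundles every tunable of the bootstrap ranking loop.
#'
#' @param alpha Acceptable test error rate in `[0,1)`; an iteration is a
#'   success only if its hold-out error is strictly below `alpha`.
#' @param beta Train split fraction in `(0,1)`; each class contributes
#'   `floor(beta * class size)` training samples, the rest test.
#' @param genes_per_iter Number of genes drawn per iteration (the small `p`
#'   of the two-way bootstrap); must stay below the training sample count.
#' @param max_iters Iteration budget `K`.
#' @param checkpoint_every Interval at which the rank order is snapshotted
#'   and compared by Spearman correlation.
#' @param rho_stop Spearman threshold in `(0,1]` that stops the run.
#' @param cv_folds Cross-validation folds for the shrinkage-threshold search.
#' @param n_thresholds Size of the shrinkage-threshold grid.
#' @param seed Integer seed; the whole run is reproducible from it.
#' @param s_update_mode Which genes are credited on a successful iteration:
#'   `"retained_only"` (genes surviving shrinkage; default) or
#'   `"all_sampled"` (every drawn gene).
#' @param classifier `"nsc"` for the real classifier, `"always_fail"` for a
#'   stub that never succeeds (diagnoses the sampling layer alone).
#' @param priors `"class"` for training-frequency priors, `"uniform"`.
#' @param gene_replace Draw genes with replacement within an iteration
#'   (off by default; duplicates add no information).
#' @return A list of class `ppea_config`.
#' @export
ppea_config <- function(alpha = 0.2, beta = 0.5, genes_per_iter = 10,
                        max_iters = 20000, checkpoint_every = 10000,
                        rho_stop = 0.999, cv_folds = 10, n_thresholds = 30,
                        seed = 1, s_update_mode = c("retained_only", "all_sampled"),
                        classifier = c("nsc", "always_fail"),
                        priors = c("class", "uniform"), gene_replace = FALSE) {
  s_update_mode <- match.arg(s_update_mode)
  classifier <- match.arg(classifier)
  priors <- match.arg(priors)
  stopifnot(alpha >= 0, alpha < 1, beta > 0, beta < 1,
            genes_per_iter >= 1, max_iters >= 0, checkpoint_every >= 1,
            rho_stop > 0, rho_stop <= 1, cv_folds >= 2, n_thresholds >= 1)
  structure(list(alpha = alpha, beta = beta,
                 genes_per_iter = as.integer(genes_per_iter),
                 max_iters = as.integer(max_iters),
                 checkpoint_every = as.integer(checkpoint_every),
                 rho_stop = rho_stop, cv_folds = as.integer(cv_folds),
                 n_thresholds = as.integer(n_thresholds),
                 seed = as.integer(seed), s_update_mode = s_update_mode,
                 classifier = classifier, priors = priors,
                 gene_replace = gene_replace),
            class = "ppea_config")
}

# p must stay below the training sample count so samples outnumber genes
validate_config <- function(config, x) {
  ns <- n_samples(x)
  m1 <- floor(config$beta * ns[["positive"]])
  m2 <- floor(config$beta * ns[["negative"]])
  if (m1 < 1 || m2 < 1 || ns[["positive"]] - m1 < 1 || ns[["negative"]] - m2 < 1) {
    abort("`beta` leaves an empty train or test set in one class.")
  }
  if (!config$gene_replace && config$genes_per_iter > nrow(x)) {
    abort("`genes_per_iter` exceeds the number of genes.")
  }
  if (config$genes_per_iter >= m1 + m2) {
    abort(sprintf(
      "`genes_per_iter` (%d) must be smaller than the training sample count (%d).",
      config$genes_per_iter, m1 + m2))
  }
  invisible(config)
}

new_performance <- function(gene_ids) {
  tibble(gene_id = as.character(gene_ids),
         T = 0L, S = 0L, R = 0,
         rank = seq_along(gene_ids))
}

#' Read / write a per-gene performance table
#'
#' The performance table holds, per gene: `T` times sampled, `S` times
#' credited in a successful model, `R = S/T` (0 where `T = 0`), and the rank
#' (1 = most predictive). Stored as TSV.
#'
#' @param perf Tibble with columns `gene_id, T, S, R, rank`.
#' @param path File path.
#' @return `read_performance()` returns the tibble; `write_performance()`
#'   returns `path` invisibly.
#' @export
write_performance <- function(perf, path) {
  stopifnot(all(c("gene_id", "T", "S", "R", "rank") %in% names(perf)))
  df <- as.data.frame(perf)
  df$R <- sprintf("%.17g", df$R)  # full precision so reals round-trip exactly
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_performance
#' @export
read_performance <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", "T", "S", "R", "rank")
  if (!all(need %in% names(df))) {
    abort("performance table must have columns gene_id, T, S, R, rank.")
  }
  out <- as_tibble(df[need])
  out$gene_id <- as.character(out$gene_id)
  out$T <- as.integer(out$T); out$S <- as.integer(out$S)
  out$R <- as.numeric(out$R)
  out$rank <- as.integer(out$rank)
  if (any(out$S > out$T)) abort("corrupt performance table: S > T.")
  out
}

#' Checkpoint a run to disk / restore it
#'
#' A checkpoint is two human-readable sidecar files sharing a stem:
#' `<path>.perf.tsv` (the performance table) and `<path>.meta.json`
#' (configuration, iteration counter, stop-criterion history, and the exact
#' random-number-generator state). Restoring and resuming reproduces an
#' uninterrupted run bit for bit.
#'
#' @param state A `ppea_fit` returned by [run_ppea()] (or a state restored
#'   by `load_checkpoint()`).
#' @param path File stem (no extension).
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   returns a `ppea_state` list suitable for `run_ppea(state = ...)`.
#' @export
save_checkpoint <- function(state, path) {
  stopifnot(inherits(state, c("ppea_fit", "ppea_state")))
  write_performance(state$performance, paste0(path, ".perf.tsv"))
  cfg <- unclass(state$config)
  # doubles go through text at 17 significant digits so they round-trip
  # bit-exactly (JSON emitters truncate to 15)
  for (f in c("alpha", "beta", "rho_stop")) cfg[[f]] <- sprintf("%.17g", cfg[[f]])
  meta <- list(
    package = "ppea", format = 1L,
    iteration = state$iteration,
    config = cfg,
    rng_kind = state$rng_kind,
    rng_state = state$rng_state,
    n_success = state$n_success,
    n_failure_tested = state$n_failure_tested,
    n_failure_no_model = state$n_failure_no_model,
    checkpoints = state$checkpoints,
    rho_history = sprintf("%.17g", state$rho_history),
    last_snapshot = state$last_snapshot,
    stopped = state$stopped)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  meta_path <- paste0(path, ".meta.json")
  perf_path <- paste0(path, ".perf.tsv")
  if (!file.exists(meta_path) || !file.exists(perf_path)) {
    abort(paste0("no checkpoint at stem '", path, "'."))
  }
  if (file.size(meta_path) == 0) abort("empty checkpoint metadata file.")
  meta <- tryCatch(jsonlite::read_json(meta_path, simplifyVector = TRUE),
                   error = function(e) abort("corrupt checkpoint metadata."))
  if (!identical(meta$package, "ppea")) abort("not a ppea checkpoint.")
  perf <- read_performance(perf_path)
  for (f in c("alpha", "beta", "rho_stop")) {
    meta$config[[f]] <- as.numeric(meta$config[[f]])
  }
  cfg <- do.call(ppea_config, meta$config)
  if (nrow(perf) < 2) abort("corrupt checkpoint: fewer than 2 genes.")
  structure(list(
    performance = perf,
    iteration = as.integer(meta$iteration),
    config = cfg,
    rng_kind = meta$rng_kind,
    rng_state = as.integer(meta$rng_state),
    n_success = as.integer(meta$n_success),
    n_failure_tested = as.integer(meta$n_failure_tested),
    n_failure_no_model = as.integer(meta$n_failure_no_model),
    checkpoints = as.integer(meta$checkpoints),
    rho_history = if (length(meta$rho_history)) as.numeric(meta$rho_history)
                  else numeric(0),
    last_snapshot = if (length(meta$last_snapshot)) as.integer(meta$last_snapshot) else NULL,
    stopped = isTRUE(meta$stopped)),
    class = "ppea_state")
}
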