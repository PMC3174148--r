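# Data preparation: informative-transcript filtering against vehicle
# controls, and ridit analysis of ordered histopathology severity grades
# used to call treatments positive or negative for a phenotype.

#' Ordered severity count table
#'
#' Grade-frequency counts for a control/reference group and a treated
#' comparison group over the same ordered categories.
#'
#' @param categories Ordered severity grades (e.g. `0:4`).
#' @param reference_counts,comparison_counts Non-negative integer counts per
#'   grade; each group must total at least 1.
#' @return A list of class `severity_table`.
#' @export
severity_table <- function(categories, reference_counts, comparison_counts) {
  stopifnot(length(categories) == length(reference_counts),
            length(categories) == length(comparison_counts))
  if (any(reference_counts < 0) || any(comparison_counts < 0)) {
    abort("counts must be non-negative.")
  }
  if (sum(reference_counts) < 1) abort("empty reference group.")
  if (sum(comparison_counts) < 1) abort("empty comparison group.")
  structure(list(categories = categories,
                 reference_counts = as.numeric(reference_counts),
                 comparison_counts = as.numeric(comparison_counts)),
            class = "severity_table")
}

#' Read a severity table from a 2-row delimited file
#'
#' Expected layout: a header row of category labels, then one row each for
#' the reference and comparison groups, with the group name in the first
#' column.
#'
#' @param path File path (`.csv` comma, else tab).
#' @return A [severity_table()].
#' @export
read_severity <- function(path) {
  df <- utils::read.delim(path, sep = delim_for(path), header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) != 2 || ncol(df) < 2) {
    abort("severity file must be 2 rows (reference, comparison) x categories.")
  }
  severity_table(categories = colnames(df)[-1],
                 reference_counts = as.numeric(df[1, -1]),
                 comparison_counts = as.numeric(df[2, -1]))
}

#' Ridit analysis of an ordered severity table
#'
#' Each category's ridit is the reference-group proportion falling below it
#' plus half the proportion within it, so the reference distribution itself
#' always averages to exactly 0.5. The comparison group's mean ridit is its
#' count-weighted average; values above 0.5 indicate a shift towards higher
#' grades relative to the reference.
#'
#' The default p-value tests mean ridit = 0.5 with the large-sample normal
#' approximation (standard error `1 / sqrt(12 * n_comparison)`), two-sided.
#' `method = "bootstrap"` instead resamples the comparison group from the
#' reference distribution under the null.
#'
#' @param table A [severity_table()].
#' @param method `"normal"` (default) or `"bootstrap"`.
#' @param B Bootstrap replicates (when `method = "bootstrap"`).
#' @param alternative `"two.sided"` (default), `"greater"` (shifted to
#'   higher grades) or `"less"`.
#' @return A list of class `ppea_ridit`: `table` (tibble with per-category
#'   counts and ridits), `mean_ridit`, `se`, `z`, `p_value`, `n_comparison`.
#' @export
#' @examples
#' tab <- severity_table(0:4, c(10, 20, 40, 20, 10), c(0, 0, 5, 10, 35))
#' ridit_scores(tab)$mean_ridit
ridit_scores <- function(table, method = c("normal", "bootstrap"), B = 2000,
                         alternative = c("two.sided", "greater", "less")) {
  stopifnot(inherits(table, "severity_table"))
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  ref <- table$reference_counts
  cmp <- table$comparison_counts
  n_ref <- sum(ref)
  n_cmp <- sum(cmp)
  ridit <- (cumsum(ref) - ref / 2) / n_ref
  mean_ridit <- sum(cmp * ridit) / n_cmp
  se <- 1 / sqrt(12 * n_cmp)
  z <- (mean_ridit - 0.5) / se
  if (method == "normal") {
    p <- switch(alternative,
                two.sided = 2 * stats::pnorm(-abs(z)),
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z))
  } else {
    boot <- colSums(rmultinom(B, n_cmp, ref / n_ref) * ridit) / n_cmp
    p_hi <- (1 + sum(boot >= mean_ridit)) / (1 + B)
    p_lo <- (1 + sum(boot <= mean_ridit)) / (1 + B)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_hi, p_lo)),
                greater = p_hi,
                less = p_lo)
  }
  structure(list(
    table = tibble(category = table$categories,
                   reference_count = ref, comparison_count = cmp,
                   ridit = ridit),
    mean_ridit = mean_ridit, se = se, z = z, p_value = p,
    n_comparison = n_cmp, method = method, alternative = alternative),
    class = "ppea_ridit")
}

#' @export
print.ppea_ridit <- function(x, ...) {
  cat(sprintf("<ppea_ridit> mean ridit %.4f (se %.4f), %s p = %.4g [%s]\n",
              x$mean_ridit, x$se, x$alternative, x$p_value, x$method))
  invisible(x)
}

#' Label a treatment from its ridit p-value and phenotype incidence
#'
#' A treatment is `positive` for the phenotype when its ridit p-value is at
#' most 0.01 and the phenotype incidence is 100%; `negative` when the
#' p-value exceeds 0.5 and the incidence is 0%; anything in between is
#' `excluded` from modeling.
#'
#' @param ridit_p Ridit p-value(s) in `[0, 1]`.
#' @param incidence_pct Phenotype incidence(s) in percent, `[0, 100]`.
#' @return Character vector in `{positive, negative, excluded}`.
#' @export
classify_treatment <- function(ridit_p, incidence_pct) {
  stopifnot(length(ridit_p) == length(incidence_pct))
  if (any(ridit_p < 0 | ridit_p > 1, na.rm = TRUE)) {
    abort("`ridit_p` must lie in [0, 1].")
  }
  if (any(incidence_pct < 0 | incidence_pct > 100, na.rm = TRUE)) {
    abort("`incidence_pct` must lie in [0, 100].")
  }
  dplyr::case_when(
    ridit_p <= 0.01 & incidence_pct == 100 ~ "positive",
    ridit_p > 0.5 & incidence_pct == 0 ~ "negative",
    .default = "excluded")
}

#' Filtering thresholds for informative transcripts
#'
#' @param min_mean_expression Minimum average expression in the treated
#'   group (default 2, on the vendor's 1-5 intensity scale).
#' @param min_abs_fold_change Minimum absolute fold change versus vehicle,
#'   with "absolute" meaning `max(ratio, 1/ratio)` (default 1.5).
#' @param max_p Maximum t-test p-value treated vs vehicle (default 0.05).
#' @param var_equal Pooled-variance Student t-test (default) or Welch when
#'   `FALSE`.
#' @return A list of class `filter_criteria`.
#' @export
filter_criteria <- function(min_mean_expression = 2,
                            min_abs_fold_change = 1.5,
                            max_p = 0.05, var_equal = TRUE) {
  stopifnot(is.finite(min_mean_expression), is.finite(min_abs_fold_change),
            min_abs_fold_change >= 1, max_p > 0, max_p < 1)
  structure(list(min_mean_expression = min_mean_expression,
                 min_abs_fold_change = min_abs_fold_change,
                 max_p = max_p, var_equal = var_equal),
            class = "filter_criteria")
}

# Vectorised two-sample t-test across genes. Zero-variance genes get p = 1
# when the group means are equal (nothing to detect) and p = 0 otherwise
# (an exact separation).
.row_ttest <- function(x1, x2, var_equal = TRUE) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  p <- 2 * stats::pt(-abs((m1 - m2) / se), df)
  degenerate <- se == 0 | !is.finite(p)
  p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
  p
}

#' Retain informative transcripts
#'
#' A transcript is informative when, simultaneously: its average expression
#' in the treated samples exceeds `min_mean_expression`; its absolute fold
#' change versus the vehicle controls (`max(ratio, 1/ratio)` of group means)
#' is at least `min_abs_fold_change`; and the treated-vs-vehicle t-test
#' p-value is below `max_p`.
#'
#' @param treated A [ppea_matrix()] (or plain genes x samples matrix) of
#'   treated samples.
#' @param vehicle Plain genes x samples matrix of matched vehicle/control
#'   samples sharing the treated gene ids.
#' @param criteria A [filter_criteria()].
#' @return A list: `matrix` (input restricted to the informative genes,
#'   keeping labels when the input had them) and `report` (one tibble row
#'   per input gene: `gene_id, mean_expression, fold_change,
#'   abs_fold_change, p_value, pass_mean, pass_fc, pass_p, informative`).
#' @export
informative_filter <- function(treated, vehicle, criteria = filter_criteria()) {
  stopifnot(inherits(criteria, "filter_criteria"))
  x <- if (inherits(treated, "ppea_matrix")) unclass(treated) else treated
  if (is.null(rownames(x)) || is.null(rownames(vehicle))) {
    abort("both matrices need gene-id rownames.")
  }
  if (!setequal(rownames(x), rownames(vehicle))) {
    abort("treated and vehicle matrices must share the same gene set.")
  }
  vehicle <- vehicle[rownames(x), , drop = FALSE]
  if (ncol(x) < 2 || ncol(vehicle) < 2) {
    abort("need at least 2 samples per group for the t-test.")
  }

  mean_tr <- rowMeans(x)
  mean_vh <- rowMeans(vehicle)
  ratio <- mean_tr / mean_vh
  abs_fc <- pmax(ratio, 1 / ratio)
  abs_fc[mean_tr == mean_vh] <- 1
  p <- .row_ttest(x, vehicle, criteria$var_equal)

  report <- tibble(
    gene_id = rownames(x),
    mean_expression = unname(mean_tr),
    fold_change = unname(ratio),
    abs_fold_change = unname(abs_fc),
    p_value = unname(p),
    pass_mean = mean_tr > criteria$min_mean_expression,
    pass_fc = abs_fc >= criteria$min_abs_fold_change,
    pass_p = p < criteria$max_p)
  report$informative <- report$pass_mean & report$pass_fc & report$pass_p

  keep <- which(report$informative)
  filtered <- if (inherits(treated, "ppea_matrix") && length(keep) >= 2) {
    subset_ppea(treated, genes = keep)
  } else {
    if (inherits(treated, "ppea_matrix") && length(keep) < 2) {
      warn("fewer than 2 informative genes; returning a plain matrix.")
    }
    x[keep, , drop = FALSE]
  }
  list(matrix = filtered, report = report)
}
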