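# Synthetic two-class expression data with a planted discriminative gene
# set, plus ordered-severity count tables. Gives every module a controlled
# input whose ground truth is known exactly.

#' Simulate a two-class expression matrix with planted markers
#'
#' Noise genes are drawn `Normal(baseline, noise_sd^2)` in both classes;
#' the first `q` genes are planted markers whose positive-class mean is
#' shifted by `effect * noise_sd`, with the shift direction alternating
#' across planted genes (up, down, up, ...) so the signal is not a single
#' direction a classifier could exploit trivially.
#'
#' @param P Total genes.
#' @param n_pos,n_neg Samples per class.
#' @param q Number of planted discriminative genes (`q <= P`).
#' @param effect Class-mean shift in units of the within-class SD.
#' @param noise_sd Within-class standard deviation.
#' @param baseline Mean expression level (log-like scale).
#' @param seed Integer seed; the same seed reproduces the matrix exactly.
#' @return A list of class `ppea_sim`: `matrix` (a [ppea_matrix()] with
#'   classes `positive`/`negative`), `planted` (character gene ids), and
#'   the generating parameters.
#' @export
#' @examples
#' sim <- simulate_two_class(P = 100, n_pos = 10, n_neg = 10, q = 5,
#'                           effect = 3, seed = 7)
#' sim$planted
simulate_two_class <- function(P, n_pos, n_neg, q, effect = 3,
                               noise_sd = 1, baseline = 8, seed = 1) {
  stopifnot(P >= 2, q >= 0, q <= P, effect >= 0, noise_sd > 0,
            n_pos >= 2, n_neg >= 2)
  gene_ids <- sprintf("g%04d", seq_len(P))
  sample_ids <- c(sprintf("pos%02d", seq_len(n_pos)),
                  sprintf("neg%02d", seq_len(n_neg)))
  labels <- rep(c("positive", "negative"), c(n_pos, n_neg))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  vals <- matrix(rnorm(P * (n_pos + n_neg), baseline, noise_sd), P,
                 dimnames = list(gene_ids, sample_ids))
  if (q > 0 && effect > 0) {
    signs <- rep_len(c(1, -1), q)
    vals[seq_len(q), seq_len(n_pos)] <-
      vals[seq_len(q), seq_len(n_pos)] + signs * effect * noise_sd
  }
  structure(list(
    matrix = ppea_matrix(vals, labels, positive = "positive"),
    planted = gene_ids[seq_len(q)],
    P = P, n_pos = n_pos, n_neg = n_neg, q = q, effect = effect,
    noise_sd = noise_sd, baseline = baseline, seed = seed),
    class = "ppea_sim")
}

#' Simulate an ordered-severity count table
#'
#' Draws multinomial grade counts for a reference and a comparison group.
#' The comparison distribution is the reference distribution exponentially
#' tilted towards higher grades: `p_j proportional to ref_j * exp(shift * j)`
#' (grades indexed 0, 1, ...), so `shift = 0` reproduces the reference
#' distribution and large `shift` pushes all mass to the top grade.
#'
#' @param categories Ordered severity grades (labels only).
#' @param reference_probs Reference-group grade probabilities (sum to 1).
#' @param shift Tilt towards higher grades (0 = none).
#' @param n_reference,n_comparison Group sizes.
#' @param seed Integer seed.
#' @return A [severity_table()].
#' @export
simulate_severity <- function(categories = 0:4,
                              reference_probs = c(0.4, 0.3, 0.15, 0.1, 0.05),
                              shift = 0, n_reference = 50, n_comparison = 50,
                              seed = 1) {
  stopifnot(length(categories) == length(reference_probs),
            all(reference_probs >= 0))
  if (abs(sum(reference_probs) - 1) > 1e-8) {
    abort("`reference_probs` must sum to 1.")
  }
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cmp_probs <- reference_probs * exp(shift * (seq_along(categories) - 1))
  cmp_probs <- cmp_probs / sum(cmp_probs)
  severity_table(
    categories = categories,
    reference_counts = as.integer(rmultinom(1, n_reference, reference_probs)),
    comparison_counts = as.integer(rmultinom(1, n_comparison, cmp_probs)))
}

#' The canonical parameter-recovery scenario
#'
#' One shared fixture used across the test suite and the worked examples:
#' 500 genes by 20 + 20 samples with 10 planted markers at a 3-SD shift
#' (alternating sign), unit noise SD, fixed seed. The planted genes are the
#' first ten gene ids. Identical across calls.
#'
#' @return A `ppea_sim`, see [simulate_two_class()].
#' @export
standard_recovery_fixture <- function() {
  simulate_two_class(P = 500, n_pos = 20, n_neg = 20, q = 10, effect = 3,
                     noise_sd = 1, baseline = 8, seed = 424242)
}

#' Write a simulated scenario to delimited files
#'
#' Writes `expression.tsv`, `labels.tsv` and `planted.tsv` under `dir`.
#'
#' @param sim A `ppea_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "ppea_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(sim$matrix, file.path(dir, "expression.tsv"),
                   file.path(dir, "labels.tsv"))
  utils::write.table(data.frame(gene_id = sim$planted),
                     file.path(dir, "planted.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
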