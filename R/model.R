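# The fitted-model interface: estimate seed-match weights from a verified
# miRNA-gene pair corpus and predict targets with them.

#' Fit seed-match weights from a verified-pair corpus
#'
#' Counts seed matches of the five types in the four gene regions over the
#' verified pairs, estimates the background expectation from repeated
#' shuffles of every region sequence, forms per-cell signal-to-noise ratios
#' and converts them to site weights anchored at the reference cell
#' (`(SNR - 1) / (SNR_ref - 1)`, reference weight 1).
#'
#' @param pairs Data frame of verified interactions with columns `mirna_id`,
#'   `gene_id`.
#' @param mirnas Named character vector of mature miRNA sequences (5'->3').
#' @param genes Named list of per-gene region sequence vectors.
#' @param n_shuffles Shuffle replicates for the background (50 in the
#'   calibration protocol; fewer is faster and noisier).
#' @param seed Master RNG seed for the shuffles.
#' @param shuffle Shuffle model, see [shuffle_sequence()].
#' @param reference Reference cell `(seed_type, region)` for the weights.
#' @return An object of class `mirtarget`: the observed and background count
#'   matrices, the `weight_table`, and the fit settings.
#' @examples
#' corpus <- generate_corpus(synth_spec(
#'   n_mirnas = 2, n_genes = 6,
#'   planted = data.frame(seed_type = "2t8A1", region = "3utr", count = 1),
#'   enrichment_factor = 3, seed = 7
#' ))
#' fit <- mirtarget(corpus$pairs, corpus$mirnas, corpus$genes,
#'                  n_shuffles = 3, seed = 7)
#' coef(fit)
#' @export
mirtarget <- function(pairs, mirnas, genes, n_shuffles = 50L, seed = 1L,
                      shuffle = c("mononucleotide", "dinucleotide"),
                      reference = c("2t8A1", "3utr")) {
  shuffle <- match.arg(shuffle)
  .check_pairs(pairs, mirnas, genes)
  if (nrow(pairs) == 0L) stop("no pairs supplied", call. = FALSE)
  observed <- count_matches(pairs, mirnas, genes)
  background <- shuffle_background(pairs, mirnas, genes,
                                   n_shuffles = n_shuffles, seed = seed,
                                   method = shuffle)
  snr <- signal_to_noise(observed, background)
  weights <- compute_weights(snr, reference = reference)
  structure(list(
    weights = weights,
    observed = observed,
    background = background,
    n_pairs = nrow(pairs),
    n_shuffles = n_shuffles,
    seed = seed,
    shuffle = shuffle,
    call = match.call()
  ), class = "mirtarget")
}

#' @export
print.mirtarget <- function(x, ...) {
  cat("Seed-match weight fit (mirtarget)\n")
  cat(sprintf("  %d verified pairs, %d %s shuffle replicate(s), seed %d\n",
              x$n_pairs, x$n_shuffles, x$shuffle, x$seed))
  cat(sprintf("  reference cell: %s / %s\n",
              x$weights$reference[["seed_type"]],
              x$weights$reference[["region"]]))
  cat("  weights:\n")
  print(round(x$weights$weights, 3L))
  invisible(x)
}

#' @export
summary.mirtarget <- function(object, ...) {
  structure(list(fit = object,
                 proportions = region_proportions(object$observed)),
            class = "summary.mirtarget")
}

#' @export
print.summary.mirtarget <- function(x, digits = 3L, ...) {
  print(x$fit)
  cat("\nObserved counts:\n")
  print(unclass(x$fit$observed))
  cat("\nBackground means:\n")
  print(round(unclass(x$fit$background), 1L))
  cat("\nSignal-to-noise ratios:\n")
  print(round(x$fit$weights$snr, digits))
  cat("\nPer-region type proportions (observed):\n")
  print(round(x$proportions, digits))
  invisible(x)
}

#' Extract the fitted weight matrix
#'
#' @param object A `mirtarget` fit.
#' @param ... Unused.
#' @return The 5 x 4 weight matrix (seed types x regions).
#' @export
coef.mirtarget <- function(object, ...) {
  object$weights$weights
}

#' Plot signal-to-noise ratios by seed type and region
#'
#' @param x A `mirtarget` fit.
#' @param ... Passed to [graphics::barplot()].
#' @return The bar midpoints, invisibly.
#' @importFrom graphics abline barplot legend
#' @export
plot.mirtarget <- function(x, ...) {
  mids <- barplot(x$weights$snr, beside = TRUE,
                  legend.text = rownames(x$weights$snr),
                  ylab = "signal-to-noise ratio", xlab = "gene region", ...)
  abline(h = 1, lty = 2)
  invisible(mids)
}

#' Predict targets from a fitted weight table
#'
#' @param object A `mirtarget` fit.
#' @param mirnas,genes Query sequences (see [predict_targets()]).
#' @param pairs Optional pair subset; default all combinations.
#' @param cutoffs A [cutoffs()] object or preset name.
#' @param params An [energy_params()] set.
#' @param details Logical; return the per-site breakdown too.
#' @param ... Unused.
#' @return See [predict_targets()].
#' @export
predict.mirtarget <- function(object, mirnas, genes, pairs = NULL,
                              cutoffs = cutoff_preset("default"),
                              params = energy_params(), details = FALSE, ...) {
  if (is.character(cutoffs)) cutoffs <- cutoff_preset(cutoffs)
  predict_targets(mirnas, genes, object$weights, pairs = pairs,
                  params = params, cutoffs = cutoffs, details = details)
}
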