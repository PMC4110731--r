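# Per-pair weighted energy totals and dual-cutoff target calls.

#' Dual energy cutoffs
#'
#' @param dG_duplex,ddG Cutoff values in kcal/mol.  Positive cutoffs are
#'   permitted but flagged with a warning since they call targets with no
#'   stabilizing sites at all.
#' @return An object of class `cutoffs`.
#' @seealso [cutoff_preset()]
#' @export
cutoffs <- function(dG_duplex, ddG) {
  stopifnot(is.finite(dG_duplex), is.finite(ddG))
  if (dG_duplex > 0 || ddG > 0) {
    warning("positive energy cutoff(s) supplied; calls will be permissive",
            call. = FALSE)
  }
  structure(list(dG_duplex = dG_duplex, ddG = ddG), class = "cutoffs")
}

#' Named cutoff presets
#'
#' `"default"` is -15.0 / -10.0 kcal/mol (total dG_duplex / total ddG),
#' tuned to yield a predicted-target count comparable to established tools;
#' `"stringent"` is -25.0 / -14.0.
#'
#' @param name Preset name.
#' @return A [cutoffs()] object.
#' @export
cutoff_preset <- function(name = c("default", "stringent")) {
  name <- match.arg(name)
  switch(name,
         default = cutoffs(-15.0, -10.0),
         stringent = cutoffs(-25.0, -14.0))
}

#' @export
print.cutoffs <- function(x, ...) {
  cat(sprintf("cutoffs: total dG_duplex < %.1f and total ddG < %.1f kcal/mol\n",
              x$dG_duplex, x$ddG))
  invisible(x)
}

.site_weight <- function(weights, seed_type, region) {
  wt <- weights$weights
  w <- wt[cbind(as.character(seed_type), as.character(region))]
  if (anyNA(w)) {
    k <- which(is.na(w))[1L]
    stop(sprintf("no weight defined for cell (%s, %s)",
                 as.character(seed_type)[k], as.character(region)[k]),
         call. = FALSE)
  }
  w
}

#' Summarize weighted energies for one miRNA-gene pair
#'
#' Every site contributes `weight(type, region) * energy` to both totals;
#' multiple sites of the same cell each contribute (per-site summation over
#' all seed matches in the entire gene sequence).  Sites in weight-0 cells
#' stay in the breakdown with zero contribution so site counts remain
#' informative.
#'
#' @param sites Data frame with columns `seed_type`, `region`, `dG_duplex`,
#'   `ddG` (one row per site, e.g. from [scan_sites()] + [site_energies()]).
#' @param weights A `weight_table` (see [compute_weights()]).
#' @param mirna_id,gene_id Optional ids.
#' @return An object of class `pair_score`: totals, site count and the
#'   per-site breakdown.
#' @export
score_pair <- function(sites, weights, mirna_id = NA_character_,
                       gene_id = NA_character_) {
  stopifnot(inherits(weights, "weight_table"))
  if (nrow(sites) == 0L) {
    breakdown <- cbind(sites[0, , drop = FALSE], weight = numeric())
    total_dup <- 0
    total_ddg <- 0
  } else {
    stopifnot(all(c("seed_type", "region", "dG_duplex", "ddG") %in% names(sites)))
    w <- .site_weight(weights, sites$seed_type, sites$region)
    breakdown <- cbind(sites, weight = w)
    total_dup <- sum(w * sites$dG_duplex)
    total_ddg <- sum(w * sites$ddG)
  }
  structure(list(mirna_id = mirna_id, gene_id = gene_id,
                 total_dG_duplex = total_dup, total_ddG = total_ddg,
                 n_sites = nrow(sites), breakdown = breakdown),
            class = "pair_score")
}

#' @export
print.pair_score <- function(x, ...) {
  cat(sprintf("pair %s ~ %s: %d site(s), total dG_duplex = %.2f, total ddG = %.2f\n",
              x$mirna_id, x$gene_id, x$n_sites, x$total_dG_duplex, x$total_ddG))
  invisible(x)
}

#' Call a putative target from summarized energies
#'
#' A pair is called a target iff both weighted totals are strictly less than
#' their cutoffs; boundary equality is a non-call.
#'
#' @param score A `pair_score`, or a data frame with columns
#'   `total_dG_duplex` and `total_ddG` (then a logical vector is returned).
#' @param cutoffs A [cutoffs()] object.
#' @return Logical.
#' @export
call_target <- function(score, cutoffs = cutoff_preset("default")) {
  stopifnot(inherits(cutoffs, "cutoffs"))
  if (inherits(score, "pair_score")) {
    score$total_dG_duplex < cutoffs$dG_duplex & score$total_ddG < cutoffs$ddG
  } else {
    score$total_dG_duplex < cutoffs$dG_duplex & score$total_ddG < cutoffs$ddG
  }
}

#' Order predictions by accessibility-corrected energy
#'
#' Ascending by `total_ddG` (most negative, i.e. most confidently bound,
#' first), ties by `total_dG_duplex`, then `gene_id`; the sort is stable.
#'
#' @param scores Data frame of pair scores.
#' @return The reordered data frame.
#' @export
rank_predictions <- function(scores) {
  if (nrow(scores) == 0L) return(scores)
  ord <- order(scores$total_ddG, scores$total_dG_duplex, scores$gene_id,
               method = "radix")
  out <- scores[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score and call targets for a set of miRNA-gene pairs
#'
#' The full pipeline behind [predict.mirtarget()]: scan each pair's regions
#' for seed sites, score each site's duplex and opening energies on its
#' flanked window, form the weighted totals and apply the dual cutoffs.
#'
#' @param mirnas Named character vector of miRNA sequences.
#' @param genes Named list of per-gene region vectors.
#' @param weights A `weight_table`.
#' @param pairs Optional data frame (`mirna_id`, `gene_id`); default is all
#'   miRNA x gene combinations.
#' @param params An [energy_params()] set.
#' @param cutoffs A [cutoffs()] object.
#' @param details Logical; also return the per-site breakdown.
#' @return A data frame with one row per pair (`mirna_id`, `gene_id`,
#'   `n_sites`, `total_dG_duplex`, `total_ddG`, `predicted`), ranked by
#'   [rank_predictions()]; with `details = TRUE`, a list with elements
#'   `scores` and `sites`.
#' @export
predict_targets <- function(mirnas, genes, weights, pairs = NULL,
                            params = energy_params(),
                            cutoffs = cutoff_preset("default"),
                            details = FALSE) {
  stopifnot(inherits(weights, "weight_table"))
  if (is.null(pairs)) {
    pairs <- expand.grid(mirna_id = names(mirnas), gene_id = names(genes),
                         stringsAsFactors = FALSE)
  }
  .check_pairs(pairs, mirnas, genes)
  scores <- vector("list", nrow(pairs))
  site_detail <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    mid <- pairs$mirna_id[k]; gid <- pairs$gene_id[k]
    sites <- scan_sites(mirnas[[mid]], genes[[gid]],
                        gene_id = gid, mirna_id = mid)
    if (nrow(sites)) {
      en <- lapply(seq_len(nrow(sites)), function(i) {
        region_seq <- genes[[gid]][[as.character(sites$region[i])]]
        win <- extract_window(region_seq, sites$start[i], sites$end[i])
        site_energies(mirnas[[mid]], win, params)
      })
      sites$dG_duplex <- vapply(en, `[[`, numeric(1L), "dG_duplex")
      sites$dG_open <- vapply(en, `[[`, numeric(1L), "dG_open")
      sites$ddG <- vapply(en, `[[`, numeric(1L), "ddG")
    } else {
      sites$dG_duplex <- numeric(0L)
      sites$dG_open <- numeric(0L)
      sites$ddG <- numeric(0L)
    }
    ps <- score_pair(sites, weights, mirna_id = mid, gene_id = gid)
    scores[[k]] <- data.frame(
      mirna_id = mid, gene_id = gid, n_sites = ps$n_sites,
      total_dG_duplex = ps$total_dG_duplex, total_ddG = ps$total_ddG,
      stringsAsFactors = FALSE
    )
    site_detail[[k]] <- ps$breakdown
  }
  scores <- do.call(rbind, scores)
  scores$predicted <- call_target(scores, cutoffs)
  scores <- rank_predictions(scores)
  if (!details) return(scores)
  list(scores = scores, sites = do.call(rbind, site_detail))
}
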