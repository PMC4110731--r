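# Shuffle-calibrated background, signal-to-noise ratios and site weights.

# Run `expr` with a private RNG state seeded by `seed`, restoring the
# caller's state afterwards so library calls never perturb user RNG streams.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Stable child seed for (seed, replicate, gene, region): a small polynomial
# string hash folded into [0, 2^31 - 2], independent of iteration order.
.child_seed <- function(seed, replicate, gene_id, region) {
  mod <- 2147483647
  h <- (as.numeric(seed) %% mod)
  h <- (h * 1103515245 + as.numeric(replicate) * 12345) %% mod
  for (ch in utf8ToInt(paste0(gene_id, "|", region))) {
    h <- (h * 131 + ch) %% mod
  }
  as.integer(h)
}

#' Randomly shuffle a sequence
#'
#' Default is a uniform mononucleotide permutation (Fisher-Yates via
#' [sample()]), which conserves the nucleotide composition exactly.  A
#' dinucleotide-preserving shuffle (random Eulerian-path resampling of the
#' dinucleotide graph) is available for composition-sensitive backgrounds but
#' is not the default.
#'
#' @param seq Normalized RNA string.
#' @param seed Integer seed; the same (sequence, seed) always yields the same
#'   shuffle and the caller's RNG state is left untouched.
#' @param method `"mononucleotide"` (default) or `"dinucleotide"`.
#' @return A shuffled sequence with identical composition (and, for the
#'   dinucleotide method, identical dinucleotide counts).
#' @export
shuffle_sequence <- function(seq, seed,
                             method = c("mononucleotide", "dinucleotide")) {
  method <- match.arg(method)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (length(chars) < 2L) return(seq)
  .with_seed(seed, {
    if (method == "mononucleotide") {
      paste(sample(chars), collapse = "")
    } else {
      paste(.dinucleotide_shuffle(chars), collapse = "")
    }
  })
}

# Altschul-Erikson dinucleotide shuffle: pick, for every vertex except the
# terminal one, a random "last" outgoing edge forming an arborescence into
# the terminal vertex (rejection sampling over a <=5-letter alphabet is
# cheap), permute the remaining edges, then walk the Eulerian path.
.dinucleotide_shuffle <- function(chars) {
  n <- length(chars)
  edges <- split(chars[-1L], chars[-n])   # vertex -> multiset of successors
  verts <- names(edges)
  last <- chars[n]
  repeat {
    last_edge <- vapply(verts, function(v) {
      if (v == last && length(edges[[v]]) == 0L) return(NA_character_)
      edges[[v]][sample.int(length(edges[[v]]), 1L)]
    }, character(1L))
    ok <- TRUE
    for (v in setdiff(verts, last)) {
      seen <- character(); cur <- v
      while (!identical(cur, last)) {
        if (cur %in% seen || !cur %in% verts) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- last_edge[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }
  walk_edges <- lapply(verts, function(v) {
    pool <- edges[[v]]
    if (v != last) {
      drop <- match(last_edge[[v]], pool)
      rest <- pool[-drop]
      c(rest[sample.int(length(rest))], last_edge[[v]])
    } else {
      pool[sample.int(length(pool))]
    }
  })
  names(walk_edges) <- verts
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1L] <- chars[1L]
  cur <- chars[1L]
  for (i in 2:n) {
    nxt <- walk_edges[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  out
}

.empty_count_matrix <- function() {
  matrix(0, nrow = length(SEED_TYPES), ncol = length(REGION_KINDS),
         dimnames = list(SEED_TYPES, REGION_KINDS))
}

.check_pairs <- function(pairs, mirnas, genes) {
  stopifnot(is.data.frame(pairs), all(c("mirna_id", "gene_id") %in% names(pairs)))
  missing_m <- setdiff(unique(pairs$mirna_id), names(mirnas))
  if (length(missing_m)) stop("unknown miRNA id in pairs: ", missing_m[1L], call. = FALSE)
  missing_g <- setdiff(unique(pairs$gene_id), names(genes))
  if (length(missing_g)) stop("unknown gene id in pairs: ", missing_g[1L], call. = FALSE)
  invisible(pairs)
}

#' Count seed matches per type and region over a pair corpus
#'
#' Counting is per site occurrence, not per gene-with-a-site: each typed
#' frame in each region of each pair contributes one count.
#'
#' @param pairs Data frame with columns `mirna_id`, `gene_id`.
#' @param mirnas Named character vector of miRNA sequences.
#' @param genes Named list of per-gene region vectors (see
#'   [read_gene_regions()]).
#' @return A 5 x 4 count matrix (seed types x regions) with attribute
#'   `n_pairs`.
#' @export
count_matches <- function(pairs, mirnas, genes) {
  .check_pairs(pairs, mirnas, genes)
  counts <- .empty_count_matrix()
  for (k in seq_len(nrow(pairs))) {
    sites <- scan_sites(mirnas[[pairs$mirna_id[k]]], genes[[pairs$gene_id[k]]])
    if (nrow(sites)) {
      counts <- counts + table(sites$seed_type, sites$region)
    }
  }
  counts <- unclass(counts)
  attr(counts, "n_pairs") <- nrow(pairs)
  counts
}

#' Average seed-match counts over shuffled replicates
#'
#' Every gene region is independently shuffled in each replicate (a gene
#' shared by several pairs is shuffled once per replicate) and the pair
#' corpus is recounted; the entrywise mean over replicates estimates the
#' background expectation.
#'
#' @inheritParams count_matches
#' @param n_shuffles Number of replicates (50 in the calibration protocol).
#' @param seed Master seed; each (replicate, gene, region) shuffle uses a
#'   stable child seed so results do not depend on iteration order.
#' @param method Shuffle model, see [shuffle_sequence()].
#' @return A 5 x 4 matrix of mean background counts with attributes
#'   `n_pairs` and `n_shuffles`.
#' @export
shuffle_background <- function(pairs, mirnas, genes, n_shuffles = 50L, seed = 1L,
                               method = c("mononucleotide", "dinucleotide")) {
  method <- match.arg(method)
  stopifnot(n_shuffles >= 1L)
  .check_pairs(pairs, mirnas, genes)
  used <- unique(pairs$gene_id)
  acc <- .empty_count_matrix()
  for (r in seq_len(n_shuffles)) {
    shuffled <- lapply(genes[used], identity)
    for (g in used) {
      for (region in names(genes[[g]])) {
        shuffled[[g]][[region]] <- shuffle_sequence(
          genes[[g]][[region]], .child_seed(seed, r, g, region), method)
      }
    }
    acc <- acc + count_matches(pairs, mirnas, shuffled)
  }
  bg <- acc / n_shuffles
  attr(bg, "n_pairs") <- nrow(pairs)
  attr(bg, "n_shuffles") <- n_shuffles
  bg
}

#' Signal-to-noise ratios of observed vs background counts
#'
#' @param observed,background 5 x 4 count matrices (seed types x regions).
#' @return 5 x 4 matrix of ratios `observed / background`; cells with zero
#'   background are `NA` (undefined) with a warning.
#' @export
signal_to_noise <- function(observed, background) {
  stopifnot(all(dim(observed) == c(5L, 4L)), all(dim(background) == c(5L, 4L)))
  snr <- unclass(observed) / unclass(background)
  attributes(snr) <- list(dim = c(5L, 4L))
  zero <- unclass(background) == 0
  if (any(zero)) {
    snr[zero] <- NA_real_
    warning("zero background in ", sum(zero),
            " cell(s); SNR undefined there and excluded from weighting",
            call. = FALSE)
  }
  dimnames(snr) <- list(SEED_TYPES, REGION_KINDS)
  snr
}

#' Convert signal-to-noise ratios to site weights
#'
#' The reference cell (by default the 2t8A1 / 3'UTR cell, the most enriched
#' combination) is assigned weight 1; every other cell gets
#' `(SNR - 1) / (SNR_ref - 1)`.  Depleted cells (SNR < 1) would give negative
#' weights; they are clamped to 0 with a warning so a depleted site type can
#' never strengthen a score.
#'
#' @param snr 5 x 4 matrix of signal-to-noise ratios.
#' @param reference Length-2 character vector `(seed_type, region)`.
#' @return An object of class `weight_table`: a list with elements `snr`,
#'   `weights` (both 5 x 4) and `reference`.
#' @export
compute_weights <- function(snr, reference = c("2t8A1", "3utr")) {
  stopifnot(all(dim(snr) == c(5L, 4L)),
            reference[1L] %in% SEED_TYPES, reference[2L] %in% REGION_KINDS)
  dimnames(snr) <- list(SEED_TYPES, REGION_KINDS)
  ref <- snr[reference[1L], reference[2L]]
  if (is.na(ref) || ref <= 1) {
    stop(sprintf("reference SNR (%s, %s) must exceed 1; got %s",
                 reference[1L], reference[2L], format(ref)), call. = FALSE)
  }
  w <- (snr - 1) / (ref - 1)
  w[reference[1L], reference[2L]] <- 1
  if (anyNA(w)) {
    warning("weights undefined for ", sum(is.na(w)), " cell(s) with undefined SNR",
            call. = FALSE)
  }
  neg <- !is.na(w) & w < 0
  if (any(neg)) {
    warning(sum(neg), " cell(s) with SNR < 1 clamped to weight 0", call. = FALSE)
    w[neg] <- 0
  }
  structure(list(snr = snr, weights = w,
                 reference = stats::setNames(reference, c("seed_type", "region"))),
            class = "weight_table")
}

#' @export
print.weight_table <- function(x, digits = 3L, ...) {
  cat("Seed-match weight table (reference ", x$reference[["seed_type"]], " / ",
      x$reference[["region"]], ")\n\nSignal-to-noise ratios:\n", sep = "")
  print(round(x$snr, digits))
  cat("\nWeights:\n")
  print(round(x$weights, digits))
  invisible(x)
}

#' Per-region proportions of the five seed-match types
#'
#' @param observed 5 x 4 count matrix.
#' @return 4 x 5 matrix (regions x seed types); each defined row sums to 1.
#'   Regions with no sites at all give an `NA` row with a warning.
#' @export
region_proportions <- function(observed) {
  stopifnot(all(dim(observed) == c(5L, 4L)))
  m <- unclass(observed)
  dimnames(m) <- list(SEED_TYPES, REGION_KINDS)
  totals <- colSums(m)
  prop <- t(m) / totals
  if (any(totals == 0)) {
    warning("region(s) with zero total sites: ",
            paste(REGION_KINDS[totals == 0], collapse = ", "), call. = FALSE)
    prop[totals == 0, ] <- NA_real_
  }
  prop
}

#' Read or write a weight table as TSV
#'
#' Long format with columns `seed_type`, `region`, `observed`,
#' `background_mean`, `snr`, `weight`; `observed`/`background_mean` may be
#' `NA` when the table was not fit from a corpus.
#'
#' @param x A `weight_table` (for writing).
#' @param path TSV path.
#' @param observed,background Optional count matrices recorded alongside.
#' @return `read_weight_table`: a `weight_table`; `write_weight_table`:
#'   `path`, invisibly.
#' @export
write_weight_table <- function(x, path, observed = NULL, background = NULL) {
  stopifnot(inherits(x, "weight_table"))
  grid <- expand.grid(seed_type = SEED_TYPES, region = REGION_KINDS,
                      stringsAsFactors = FALSE)
  idx <- cbind(grid$seed_type, grid$region)
  df <- data.frame(
    grid,
    observed = if (is.null(observed)) NA_real_ else unclass(observed)[idx],
    background_mean = if (is.null(background)) NA_real_ else unclass(background)[idx],
    snr = x$snr[idx],
    weight = x$weights[idx]
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weight_table
#' @export
read_weight_table <- function(path) {
  if (!file.exists(path)) stop("weight table not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("seed_type", "region", "snr", "weight")
  if (!all(need %in% names(df))) {
    stop("weight table ", path, " lacks column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  snr <- .empty_count_matrix(); w <- .empty_count_matrix()
  snr[] <- NA_real_; w[] <- NA_real_
  idx <- cbind(df$seed_type, df$region)
  snr[idx] <- df$snr
  w[idx] <- df$weight
  ref_idx <- which(w == 1, arr.ind = TRUE)
  reference <- if (nrow(ref_idx)) {
    c(SEED_TYPES[ref_idx[1L, 1L]], REGION_KINDS[ref_idx[1L, 2L]])
  } else c("2t8A1", "3utr")
  structure(list(snr = snr, weights = w,
                 reference = stats::setNames(reference, c("seed_type", "region"))),
            class = "weight_table")
}

#' Published seed-match weights from the curated miRWalk corpus
#'
#' Recomputes the weight table from the bundled per-type, per-region
#' observed and 50-shuffle background counts of the curated miRWalk-verified
#' corpus (655 human miRNAs against their verified genes); the weights are
#' always derived by [signal_to_noise()] + [compute_weights()], never stored.
#'
#' @return A `weight_table`, with the count matrices attached as attributes
#'   `observed` and `background`.
#' @export
published_weights <- function() {
  path <- system.file("extdata", "mirwalk_counts.tsv", package = "mirtarget",
                      mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  obs <- .empty_count_matrix(); bg <- .empty_count_matrix()
  idx <- cbind(df$seed_type, df$region)
  obs[idx] <- df$observed
  bg[idx] <- df$background_mean
  wt <- compute_weights(signal_to_noise(obs, bg))
  attr(wt, "observed") <- obs
  attr(wt, "background") <- bg
  wt
}
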