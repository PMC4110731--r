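# Synthetic corpus generator: i.i.d. background gene regions with planted,
# unambiguous seed sites recorded in a ledger, for calibration and testing
# without any external downloads.

#' Specification for a synthetic corpus
#'
#' The generator draws i.i.d. mononucleotide background sequences (matching
#' the shuffle null by construction) and plants exact seed sites of chosen
#' types on top.  `enrichment_factor` is the target fold-enrichment of the
#' planted cell over its background baseline: for each `planted` row,
#' `round(count * (enrichment_factor - 1))` sites are planted per pair, so a
#' factor of 1 plants nothing (a pure-null corpus) and a factor of 3 with
#' `count = 1` plants two sites per pair on top of whatever the background
#' composition produces by chance.
#'
#' @param n_mirnas,n_genes Corpus dimensions; pairs are formed by cycling
#'   the miRNAs over the genes (one pair per gene).
#' @param region_lengths Named integer vector of region lengths (all four
#'   regions, each >= 60 so full flanked windows exist).
#' @param composition Background nucleotide probabilities (A, C, G, U),
#'   summing to 1.
#' @param planted Data frame with columns `seed_type`, `region`, `count`
#'   (count per pair), or `NULL` for no planting.
#' @param enrichment_factor Fold-enrichment of planted cells (>= 1).
#' @param mirna_length Length of generated miRNAs.
#' @param seed RNG seed; the corpus is a deterministic function of the spec.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_mirnas, n_genes,
                       region_lengths = c(promoter = 200L, `5utr` = 150L,
                                          cds = 300L, `3utr` = 300L),
                       composition = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25),
                       planted = NULL, enrichment_factor = 1,
                       mirna_length = 22L, seed = 1L) {
  stopifnot(n_mirnas >= 1L, n_genes >= 1L, mirna_length >= 8L,
            enrichment_factor >= 1)
  if (!all(REGION_KINDS %in% names(region_lengths))) {
    stop("region_lengths must name all of: ",
         paste(REGION_KINDS, collapse = ", "), call. = FALSE)
  }
  if (any(region_lengths < 60L)) {
    stop("region lengths must be >= 60 so full flanked windows exist",
         call. = FALSE)
  }
  if (!all(c("A", "C", "G", "U") %in% names(composition)) ||
      abs(sum(composition) - 1) > 1e-9 || any(composition < 0)) {
    stop("composition must be probabilities over A, C, G, U summing to 1",
         call. = FALSE)
  }
  if (!is.null(planted)) {
    stopifnot(is.data.frame(planted),
              all(c("seed_type", "region", "count") %in% names(planted)),
              all(planted$seed_type %in% SEED_TYPES),
              all(planted$region %in% REGION_KINDS),
              all(planted$count >= 0))
  }
  structure(list(n_mirnas = as.integer(n_mirnas), n_genes = as.integer(n_genes),
                 region_lengths = region_lengths[REGION_KINDS],
                 composition = composition[c("A", "C", "G", "U")],
                 planted = planted, enrichment_factor = enrichment_factor,
                 mirna_length = as.integer(mirna_length),
                 seed = as.integer(seed)),
            class = "synth_spec")
}

.WC_CHAR <- c(A = "U", C = "G", G = "C", U = "A")
.GU_CHAR <- c(G = "U", U = "G")

.random_seq <- function(n, composition) {
  paste(sample(names(composition), n, replace = TRUE, prob = composition),
        collapse = "")
}

# The exact 8-nt target frame realizing `type` for this miRNA, built so the
# frame classifies to exactly the requested type (never a stronger one).
.planted_frame <- function(m8, type) {
  frame <- character(8L)
  wc_at <- function(p) .WC_CHAR[[m8[p]]]
  for (p in 2:8) frame[9L - p] <- wc_at(p)
  if (type == "2t8A1") {
    frame[8L] <- "A"
  } else if (type == "2t8") {
    frame[8L] <- sample(c("C", "G", "U"), 1L)
  } else if (type %in% c("2t7A1", "2t7")) {
    frame[8L] <- if (type == "2t7A1") "A" else sample(c("C", "G", "U"), 1L)
    frame[1L] <- sample(setdiff(c("A", "C", "G", "U"), wc_at(8L)), 1L)
  } else if (type == "1t8GU") {
    cand <- which(m8[2:7] %in% c("G", "U")) + 1L
    if (length(cand) == 0L) {
      stop("miRNA seed has no G/U at positions 2-7; cannot plant 1t8GU",
           call. = FALSE)
    }
    w <- cand[sample.int(length(cand), 1L)]
    frame[9L - 1L] <- wc_at(1L)
    frame[9L - w] <- .GU_CHAR[[m8[w]]]
  } else {
    stop("unknown seed type: ", type, call. = FALSE)
  }
  paste(frame, collapse = "")
}

#' Generate a synthetic corpus with a planted-site ledger
#'
#' Planted frames are placed at non-overlapping random offsets; each frame is
#' constructed so that it classifies to exactly the requested type (flanking
#' nucleotides that would upgrade the match are never drawn, since the frame
#' classifier only looks at the 8-nt frame itself).  When `1t8GU` planting is
#' requested, miRNAs are resampled until their seed carries a G or U at
#' positions 2-7 so a wobble frame exists.
#'
#' @param spec A [synth_spec()].
#' @return A list: `mirnas` (named character vector), `genes` (named list of
#'   region vectors), `pairs` (data frame `mirna_id`, `gene_id`), `ledger`
#'   (data frame of every planted site: `mirna_id`, `gene_id`, `region`,
#'   `start`, `end`, `seed_type` using the same span convention as
#'   [scan_sites()]), and `spec`.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  .with_seed(spec$seed, .generate_corpus_impl(spec))
}

.generate_corpus_impl <- function(spec) {
  need_gu <- !is.null(spec$planted) && any(spec$planted$seed_type == "1t8GU" &
                                             spec$planted$count > 0)
  mirnas <- character(spec$n_mirnas)
  for (i in seq_len(spec$n_mirnas)) {
    repeat {
      s <- .random_seq(spec$mirna_length, spec$composition)
      if (!need_gu || any(strsplit(substr(s, 2L, 7L), "")[[1L]] %in% c("G", "U")))
        break
    }
    mirnas[i] <- s
  }
  names(mirnas) <- sprintf("mir%03d", seq_len(spec$n_mirnas))

  genes <- vector("list", spec$n_genes)
  names(genes) <- sprintf("gene%04d", seq_len(spec$n_genes))
  for (g in names(genes)) {
    genes[[g]] <- vapply(REGION_KINDS, function(r) {
      .random_seq(spec$region_lengths[[r]], spec$composition)
    }, character(1L))
  }

  pairs <- data.frame(
    mirna_id = names(mirnas)[((seq_len(spec$n_genes) - 1L) %% spec$n_mirnas) + 1L],
    gene_id = names(genes),
    stringsAsFactors = FALSE
  )

  ledger <- list()
  if (!is.null(spec$planted)) {
    copies <- round(spec$planted$count * (spec$enrichment_factor - 1))
    for (k in seq_len(nrow(pairs))) {
      mid <- pairs$mirna_id[k]; gid <- pairs$gene_id[k]
      m8 <- strsplit(substr(mirnas[[mid]], 1L, 8L), "")[[1L]]
      occupied <- lapply(spec$region_lengths, function(L) rep(FALSE, L))
      for (p in seq_len(nrow(spec$planted))) {
        if (copies[p] == 0L) next
        region <- spec$planted$region[p]
        type <- spec$planted$seed_type[p]
        L <- spec$region_lengths[[region]]
        for (cp in seq_len(copies[p])) {
          free <- which(vapply(seq_len(L - 7L), function(s) {
            !any(occupied[[region]][s:(s + 7L)])
          }, logical(1L)))
          if (length(free) == 0L) {
            stop(sprintf(
              "region %s (%d nt) too short to host %d planted site(s)",
              region, L, copies[p]), call. = FALSE)
          }
          s <- free[sample.int(length(free), 1L)]
          occupied[[region]][s:(s + 7L)] <- TRUE
          frame <- .planted_frame(m8, type)
          seq <- genes[[gid]][[region]]
          substr(seq, s, s + 7L) <- frame
          genes[[gid]][[region]] <- seq
          frame0 <- s - 1L
          ledger[[length(ledger) + 1L]] <- data.frame(
            mirna_id = mid, gene_id = gid, region = region,
            start = frame0 + .SITE_OFFSET[[type]],
            end = frame0 + .SITE_OFFSET[[type]] + .SITE_LENGTH[[type]],
            seed_type = type, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  ledger <- if (length(ledger)) do.call(rbind, ledger) else data.frame(
    mirna_id = character(), gene_id = character(), region = character(),
    start = integer(), end = integer(), seed_type = character(),
    stringsAsFactors = FALSE
  )
  list(mirnas = mirnas, genes = genes, pairs = pairs, ledger = ledger,
       spec = spec)
}
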