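# Seed-match scanning: find and type all seed sites of a miRNA in a region.
#
# A "frame" is the 8-nt target window whose 3'-most nucleotide lies opposite
# miRNA position 1 (strands antiparallel, both written 5'->3').  Every frame
# is classified once; the canonical types take precedence in the order
# 2t8A1 > 2t8 > 2t7A1 > 2t7, and 1t8GU (all eight positions paired with
# exactly one G:U wobble) is reported only when no canonical type applies,
# which keeps the five types disjoint and the per-type counts well-defined.

# Watson-Crick partner of each encoded nucleotide (A C G U N); NA = none.
.WC_PARTNER <- c(4L, 3L, 2L, 1L, NA_integer_)
# G:U wobble partner: G pairs U, U pairs G.
.GU_PARTNER <- c(NA_integer_, NA_integer_, 4L, 3L, NA_integer_)

# Site span convention relative to the frame start (0-based, half-open):
# the span covers the target nucleotides opposite the miRNA positions named
# by the type (plus the A1 anchor where required), giving lengths 8/7/7/6/8.
.SITE_OFFSET <- c(`2t8A1` = 0L, `2t8` = 0L, `2t7A1` = 1L, `2t7` = 1L, `1t8GU` = 0L)
.SITE_LENGTH <- c(`2t8A1` = 8L, `2t8` = 7L, `2t7A1` = 7L, `2t7` = 6L, `1t8GU` = 8L)

#' Test antiparallel Watson-Crick pairing of two windows
#'
#' Both windows are written 5'->3'; target position k is opposite miRNA
#' position `L + 1 - k`.  Every opposing pair must be one of A:U, U:A, G:C,
#' C:G; G:U is not Watson-Crick and N never pairs.
#'
#' @param mirna_window,target_window Equal-length RNA strings.
#' @return `TRUE` iff all opposing positions form Watson-Crick pairs.
#' @export
site_pairs_wc <- function(mirna_window, target_window) {
  m <- .encode_nt(normalize_sequence(mirna_window, what = "miRNA window"))
  t <- .encode_nt(normalize_sequence(target_window, what = "target window"))
  if (length(m) != length(t)) {
    stop("window length mismatch: ", length(m), " vs ", length(t), call. = FALSE)
  }
  partner <- .WC_PARTNER[m]
  all(!is.na(partner) & rev(t) == partner)
}

# Vectorized frame classifier over one region.  Returns integer type per
# frame offset (0 = none, otherwise index into SEED_TYPES) plus the G:U
# wobble matrix needed to report wobble positions.
.classify_frames <- function(m8, tint) {
  L <- length(tint)
  if (L < 8L) {
    return(list(type = integer(0L), gu = matrix(FALSE, 8L, 0L)))
  }
  noff <- L - 7L
  s <- seq_len(noff)
  wc <- matrix(FALSE, 8L, noff)
  gu <- matrix(FALSE, 8L, noff)
  for (p in 1:8) {
    opp <- tint[s + 8L - p]        # target nt opposite miRNA position p
    wp <- .WC_PARTNER[m8[p]]
    gp <- .GU_PARTNER[m8[p]]
    wc[p, ] <- !is.na(wp) & opp == wp
    if (!is.na(gp)) gu[p, ] <- opp == gp
  }
  a1 <- tint[s + 7L] == 1L         # adenine opposite miRNA position 1
  wc28 <- colSums(wc[2:8, , drop = FALSE]) == 7L
  wc27 <- colSums(wc[2:7, , drop = FALSE]) == 6L
  type <- integer(noff)
  type[wc27] <- 4L
  type[wc27 & a1] <- 3L
  type[wc28] <- 2L
  type[wc28 & a1] <- 1L
  wobble1 <- type == 0L &
    colSums(wc | gu) == 8L &
    colSums(gu) == 1L
  type[wobble1] <- 5L
  list(type = type, gu = gu)
}

#' Classify one 8-nt target window against a miRNA seed
#'
#' @param mirna miRNA sequence (5'->3', at least 8 nt).
#' @param target8 The 8-nt target window whose 3'-most nucleotide is opposite
#'   miRNA position 1.
#' @return A list with `seed_type` and `wobble_pos` (miRNA position of the
#'   G:U wobble, `NA` unless the type is `1t8GU`), or `NULL` when no seed
#'   type applies.
#' @export
classify_window <- function(mirna, target8) {
  m <- .encode_nt(normalize_sequence(mirna, allow_n = FALSE, what = "miRNA"))
  if (length(m) < 8L) stop("miRNA shorter than 8 nt", call. = FALSE)
  t <- .encode_nt(normalize_sequence(target8, what = "target window"))
  if (length(t) != 8L) {
    stop("target window must be exactly 8 nt, got ", length(t), call. = FALSE)
  }
  cl <- .classify_frames(m[1:8], t)
  if (cl$type == 0L) return(NULL)
  list(
    seed_type = SEED_TYPES[cl$type],
    wobble_pos = if (cl$type == 5L) which(cl$gu[, 1L]) else NA_integer_
  )
}

#' Scan all gene regions for seed-match sites
#'
#' Every full 8-nt frame in every present region is classified; frames whose
#' 8-nt context would extend past a region end are not reported.  Overlapping
#' sites at different offsets are all kept.
#'
#' @param mirna miRNA sequence (5'->3').
#' @param regions Named character vector of region sequences (names among
#'   `promoter`, `5utr`, `cds`, `3utr`), e.g. from [gene_regions()].
#' @param gene_id,mirna_id Optional ids copied into the output.
#' @return A data frame sorted by (region, start) with columns `mirna_id`,
#'   `gene_id`, `region`, `start`, `end` (0-based half-open on the region's
#'   sense strand), `strand`, `seed_type` and `wobble_pos`.
#' @export
scan_sites <- function(mirna, regions, gene_id = NA_character_,
                       mirna_id = NA_character_) {
  m <- .encode_nt(normalize_sequence(mirna, allow_n = FALSE, what = "miRNA"))
  if (length(m) < 8L) stop("miRNA shorter than 8 nt", call. = FALSE)
  m8 <- m[1:8]
  out <- vector("list", length(REGION_KINDS))
  for (region in intersect(REGION_KINDS, names(regions))) {
    tint <- .encode_nt(regions[[region]])
    cl <- .classify_frames(m8, tint)
    hit <- which(cl$type > 0L)
    if (length(hit) == 0L) next
    type <- cl$type[hit]
    frame0 <- hit - 1L
    wobble <- rep(NA_integer_, length(hit))
    is_gu <- type == 5L
    if (any(is_gu)) {
      wobble[is_gu] <- vapply(hit[is_gu], function(k) which(cl$gu[, k]),
                              integer(1L))
    }
    out[[region]] <- data.frame(
      mirna_id = mirna_id,
      gene_id = gene_id,
      region = region,
      start = frame0 + .SITE_OFFSET[type],
      end = frame0 + .SITE_OFFSET[type] + .SITE_LENGTH[type],
      strand = "+",
      seed_type = SEED_TYPES[type],
      wobble_pos = wobble,
      stringsAsFactors = FALSE,
      row.names = NULL
    )
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    mirna_id = character(), gene_id = character(), region = character(),
    start = integer(), end = integer(), strand = character(),
    seed_type = character(), wobble_pos = integer(),
    stringsAsFactors = FALSE
  )
  res$region <- factor(res$region, levels = REGION_KINDS)
  res$seed_type <- factor(res$seed_type, levels = SEED_TYPES)
  rownames(res) <- NULL
  res
}
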