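# Sequence model: RNA alphabet, FASTA ingestion, isoform resolution.

#' @useDynLib mirtarget, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Region enum, in scanning/report order.  Serialized names are stable.
REGION_KINDS <- c("promoter", "5utr", "cds", "3utr")

# Seed-match types, in precedence order for the canonical four; the G:U-wobble
# type is classified only when no canonical type applies.
SEED_TYPES <- c("2t8A1", "2t8", "2t7A1", "2t7", "1t8GU")

# Integer encoding used throughout (N = 5 never pairs).
NT_LEVELS <- c("A", "C", "G", "U", "N")

.encode_nt <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1L]], NT_LEVELS)
}

#' Normalize a nucleotide sequence to the RNA alphabet
#'
#' Uppercases, converts T to U, and validates that every character is one of
#' A, C, G, U or N.  All sequences handled by the package pass through this
#' normalization, so downstream code can assume a clean RNA alphabet.
#'
#' @param raw A single character string.
#' @param allow_n Logical; permit ambiguous `N` characters (the default).
#'   Mature miRNA sequences are read with `allow_n = FALSE` since an
#'   ambiguous base in the seed would make every match undecidable.
#' @param what Label used in error messages (e.g. a record id).
#' @return The normalized sequence (uppercase RNA).
#' @examples
#' normalize_sequence("acgt")  # "ACGU"
#' @export
normalize_sequence <- function(raw, allow_n = TRUE, what = "sequence") {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || !nzchar(raw)) {
    stop(what, ": empty or missing sequence", call. = FALSE)
  }
  s <- chartr("tT", "uU", raw)
  s <- toupper(s)
  alphabet <- if (allow_n) c("A", "C", "G", "U", "N") else c("A", "C", "G", "U")
  ok <- strsplit(s, "", fixed = TRUE)[[1L]] %in% alphabet
  if (!all(ok)) {
    pos <- which(!ok)[1L]
    stop(sprintf("%s: illegal character '%s' at position %d",
                 what, substr(raw, pos, pos), pos), call. = FALSE)
  }
  s
}

#' Read a FASTA file
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that preserves record
#' order, concatenates multi-line records, normalizes sequences to the RNA
#' alphabet and reports empty records with their line number.
#'
#' @param path Path to a plain (optionally multi-line) FASTA file.
#' @param allow_n Passed to [normalize_sequence()].
#' @return A named character vector of normalized sequences; names are the
#'   full header lines (without the leading `>`), possibly duplicated when a
#'   gene has several isoforms.
#' @export
read_fasta <- function(path, allow_n = TRUE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop(sprintf("FASTA parse error in '%s' (line %d): %s",
                   path, .first_bad_fasta_line(path), conditionMessage(e)),
           call. = FALSE)
    }
  )
  seqs <- as.character(set)
  if (any(!nzchar(seqs))) {
    bad <- names(set)[which(!nzchar(seqs))[1L]]
    stop(sprintf("FASTA parse error in '%s' (line %d): empty record '%s'",
                 path, .fasta_header_line(path, bad), bad), call. = FALSE)
  }
  out <- vapply(seq_along(seqs), function(i) {
    normalize_sequence(seqs[[i]], allow_n = allow_n,
                       what = sprintf("%s record '%s'", path, names(set)[i]))
  }, character(1L))
  names(out) <- names(set)
  out
}

# Line number of the first structural problem (no leading '>', or nothing at
# all); only consulted when Biostrings has already refused the file.
.first_bad_fasta_line <- function(path) {
  lines <- tryCatch(readLines(path, warn = FALSE), error = function(e) character())
  if (length(lines) == 0L) return(1L)
  if (!startsWith(lines[1L], ">")) return(1L)
  length(lines)
}

.fasta_header_line <- function(path, header) {
  lines <- readLines(path, warn = FALSE)
  hit <- which(lines == paste0(">", header))
  if (length(hit)) hit[1L] else 1L
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::BStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Keep the longest isoform per gene
#'
#' Gene-region FASTA exports often carry several transcript isoforms per gene;
#' one representative sequence per gene is kept: the longest, with ties broken
#' by the lexicographically smallest sequence and then by first occurrence, so
#' the choice is deterministic.
#'
#' @param seqs Named character vector; names are gene ids (duplicates mark
#'   isoforms).
#' @return Named character vector with unique names, in order of each gene's
#'   first appearance.
#' @export
select_longest_isoform <- function(seqs) {
  if (length(seqs) == 0L) return(stats::setNames(character(), character()))
  ids <- names(seqs)
  if (is.null(ids)) stop("sequences must be named by gene id", call. = FALSE)
  first <- ids[!duplicated(ids)]
  picked <- vapply(first, function(g) {
    cand <- seqs[ids == g]
    cand <- cand[nchar(cand) == max(nchar(cand))]
    cand <- cand[cand == min(cand)]
    cand[[1L]]
  }, character(1L))
  stats::setNames(picked, first)
}

# Header-token conventions: gene id is the first whitespace-delimited token;
# an optional '|region' suffix selects the region in a combined file.
.header_token <- function(headers) {
  vapply(strsplit(headers, "[ \t]+"), `[[`, character(1L), 1L)
}

.split_region_suffix <- function(tokens) {
  parts <- strsplit(tokens, "|", fixed = TRUE)
  data.frame(
    gene_id = vapply(parts, `[[`, character(1L), 1L),
    region = vapply(parts, function(p) if (length(p) > 1L) p[[2L]] else NA_character_,
                    character(1L)),
    stringsAsFactors = FALSE
  )
}

#' Read mature miRNA sequences from FASTA
#'
#' Sequences are normalized (T to U, uppercase), must be at least 8 nt long
#' (positions 1-8 define the seed) and may not contain N.
#'
#' @param path FASTA path.
#' @return Named character vector keyed by miRNA id (first header token).
#' @export
read_mirna_fasta <- function(path) {
  seqs <- read_fasta(path, allow_n = FALSE)
  names(seqs) <- .header_token(names(seqs))
  short <- nchar(seqs) < 8L
  if (any(short)) {
    stop(sprintf("miRNA '%s' is shorter than 8 nt", names(seqs)[which(short)[1L]]),
         call. = FALSE)
  }
  if (anyDuplicated(names(seqs))) {
    stop("duplicated miRNA id: ", names(seqs)[duplicated(names(seqs))][1L],
         call. = FALSE)
  }
  seqs
}

#' Assemble per-gene region sequences from FASTA files
#'
#' Accepts one FASTA per region and/or a combined file whose header tokens
#' carry a `|region` suffix (region names `promoter`, `5utr`, `cds`, `3utr`).
#' When a gene has several isoforms within a region, the longest is kept
#' (per region, independently across regions).
#'
#' @param promoter,utr5,cds,utr3 Optional per-region FASTA paths.
#' @param combined Optional combined FASTA path with `|region` suffixes.
#' @return A named list: for each gene id, a named character vector of the
#'   regions present for that gene.
#' @export
read_gene_regions <- function(promoter = NULL, utr5 = NULL, cds = NULL,
                              utr3 = NULL, combined = NULL) {
  per_region <- list(promoter = promoter, `5utr` = utr5, cds = cds, `3utr` = utr3)
  pool <- list()  # region -> named char vector (possibly duplicated gene ids)
  for (region in names(per_region)) {
    if (!is.null(per_region[[region]])) {
      seqs <- read_fasta(per_region[[region]])
      names(seqs) <- .split_region_suffix(.header_token(names(seqs)))$gene_id
      pool[[region]] <- c(pool[[region]], seqs)
    }
  }
  if (!is.null(combined)) {
    seqs <- read_fasta(combined)
    info <- .split_region_suffix(.header_token(names(seqs)))
    if (anyNA(info$region)) {
      stop("combined FASTA headers must carry a '|region' suffix; first offender: ",
           names(seqs)[which(is.na(info$region))[1L]], call. = FALSE)
    }
    bad <- !info$region %in% REGION_KINDS
    if (any(bad)) {
      stop("unknown region '", info$region[which(bad)[1L]],
           "' (expected one of ", paste(REGION_KINDS, collapse = ", "), ")",
           call. = FALSE)
    }
    for (region in unique(info$region)) {
      sel <- info$region == region
      pool[[region]] <- c(pool[[region]],
                          stats::setNames(seqs[sel], info$gene_id[sel]))
    }
  }
  if (length(pool) == 0L) stop("no region FASTA supplied", call. = FALSE)
  pool <- lapply(pool, select_longest_isoform)

  genes <- list()
  for (region in intersect(REGION_KINDS, names(pool))) {
    for (g in names(pool[[region]])) {
      genes[[g]][[region]] <- pool[[region]][[g]]
    }
  }
  lapply(genes, unlist)
}

#' Construct a per-gene region-sequence record
#'
#' @param promoter,utr5,cds,utr3 Optional region sequences (any subset).
#' @return Named character vector of normalized region sequences.
#' @export
gene_regions <- function(promoter = NULL, utr5 = NULL, cds = NULL, utr3 = NULL) {
  given <- list(promoter = promoter, `5utr` = utr5, cds = cds, `3utr` = utr3)
  given <- given[!vapply(given, is.null, logical(1L))]
  if (length(given) == 0L) stop("at least one region sequence required", call. = FALSE)
  vapply(names(given), function(r) {
    normalize_sequence(given[[r]], what = paste0("region ", r))
  }, character(1L))
}
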