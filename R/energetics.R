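# Site energetics: duplex hybridization (dG_duplex), target-site opening
# cost (dG_open) and accessibility-corrected energy (ddG) on the flanked
# site window.  The engine is a pair of nearest-neighbor dynamic programs
# (intermolecular duplex with intramolecular pairing forbidden; constrained
# intramolecular folding with minimum hairpin loop 3), parameterized by a
# versioned data file.

.PAIR_NAMES <- c("AU", "UA", "GC", "CG", "GU", "UG")

#' Load an energy parameter set
#'
#' Parameter files are TSV with columns `category`, `name`, `value`:
#' `stack` rows name a 5'-pair/3'-pair combination (`XY-ZW`, top strand
#' letters first); `scalar` rows give the duplex initiation term and the
#' affine loop penalties.  Stack entries may be given for one member of each
#' symmetric pair of stacks; the loader completes the table by symmetry.
#'
#' @param path Path to a parameter TSV; `NULL` loads the bundled reduced
#'   nearest-neighbor set (`nn-reduced-1.0`).
#' @return An object of class `energy_params`.
#' @export
energy_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "energy_params_nn_reduced.tsv",
                        package = "mirtarget", mustWork = TRUE)
  }
  if (!file.exists(path)) stop("energy parameter file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  version <- sub("^#\\s*parameter_set:\\s*", "", header)
  if (identical(version, header)) version <- "unversioned"
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  stacks <- matrix(NA_real_, 6L, 6L, dimnames = list(.PAIR_NAMES, .PAIR_NAMES))
  flip <- c(AU = "UA", UA = "AU", GC = "CG", CG = "GC", GU = "UG", UG = "GU")
  st <- df[df$category == "stack", ]
  for (k in seq_len(nrow(st))) {
    pq <- strsplit(st$name[k], "-", fixed = TRUE)[[1L]]
    if (length(pq) != 2L || !all(pq %in% .PAIR_NAMES)) {
      stop("malformed stack name '", st$name[k], "' in ", path, call. = FALSE)
    }
    v <- as.numeric(st$value[k])
    stacks[pq[1L], pq[2L]] <- v
    mirror <- c(flip[[pq[2L]]], flip[[pq[1L]]])
    if (is.na(stacks[mirror[1L], mirror[2L]])) stacks[mirror[1L], mirror[2L]] <- v
  }
  if (anyNA(stacks)) {
    stop("incomplete stack table in ", path, " (",
         sum(is.na(stacks)), " undefined combinations)", call. = FALSE)
  }
  sc <- df[df$category == "scalar", ]
  scalars <- stats::setNames(as.numeric(sc$value), sc$name)
  need <- c("duplex_init", "bulge_open", "bulge_ext", "il_open", "il_ext",
            "hairpin_open", "hairpin_ext", "ml_open", "ml_branch", "ml_unpaired")
  if (!all(need %in% names(scalars))) {
    stop("missing scalar parameter(s) in ", path, ": ",
         paste(setdiff(need, names(scalars)), collapse = ", "), call. = FALSE)
  }
  structure(c(list(version = version, stacks = stacks), as.list(scalars[need])),
            class = "energy_params")
}

#' @export
print.energy_params <- function(x, ...) {
  cat("Energy parameter set '", x$version, "': 6x6 stack table, duplex init ",
      format(x$duplex_init), " kcal/mol, affine loop penalties\n", sep = "")
  invisible(x)
}

#' Uniform toy energy parameters
#'
#' A deliberately simple set used for worked examples and enumeration
#' cross-checks: every stack has the same energy, loops cost a flat per-
#' nucleotide penalty and there is no initiation term.
#'
#' @param stack Stack energy (kcal/mol) for every pair combination.
#' @param loop_ext Per-nucleotide loop penalty.
#' @return An `energy_params` object.
#' @export
toy_energy_params <- function(stack = -3, loop_ext = 4) {
  structure(list(
    version = "toy",
    stacks = matrix(stack, 6L, 6L, dimnames = list(.PAIR_NAMES, .PAIR_NAMES)),
    duplex_init = 0, bulge_open = 0, bulge_ext = loop_ext,
    il_open = 0, il_ext = loop_ext, hairpin_open = 0, hairpin_ext = loop_ext,
    ml_open = 0, ml_branch = 0, ml_unpaired = loop_ext
  ), class = "energy_params")
}

#' Extract the flanked window around a seed site
#'
#' The scored context is the site plus up to 30 nt of 5' flank and up to
#' 20 nt of 3' flank, truncated at the region ends (58 nt for a full-context
#' 8-nt site).
#'
#' @param region_seq Region sequence (5'->3').
#' @param start,end Site span, 0-based half-open on `region_seq`.
#' @return A list with `sequence`, `site_start`, `site_end` (span within the
#'   window, 0-based half-open) and `window_start` (window offset on the
#'   region).
#' @export
extract_window <- function(region_seq, start, end) {
  L <- nchar(region_seq)
  stopifnot(start >= 0L, end > start, end <= L)
  flank5 <- min(30L, start)
  win_start <- start - flank5
  win_end <- min(L, end + 20L)
  list(
    sequence = substr(region_seq, win_start + 1L, win_end),
    site_start = flank5,
    site_end = flank5 + (end - start),
    window_start = win_start
  )
}

.window_seq <- function(window) {
  if (is.list(window)) window$sequence else window
}

#' Minimum free energy of the miRNA:window duplex
#'
#' Hybridization MFE of the full miRNA against the site window: all
#' antiparallel duplex structures with Watson-Crick and G:U pairs, stacks
#' scored by the nearest-neighbor table, bulge/interior gaps by affine
#' penalties; intramolecular pairing is forbidden.  The empty duplex has
#' energy 0, so the value is never positive.
#'
#' @param mirna miRNA sequence.
#' @param window A window from [extract_window()] or a plain sequence.
#' @param params An [energy_params()] set.
#' @return MFE in kcal/mol.
#' @export
duplex_energy <- function(mirna, window, params = energy_params()) {
  stopifnot(inherits(params, "energy_params"))
  mi <- .encode_nt(normalize_sequence(mirna, what = "miRNA"))
  tg <- .encode_nt(normalize_sequence(.window_seq(window), what = "window"))
  if (length(mi) < 2L || length(tg) < 2L) {
    stop("duplex requires both sequences to be at least 2 nt", call. = FALSE)
  }
  duplex_mfe_cpp(mi, tg, params$stacks, params$duplex_init,
                 params$bulge_open, params$bulge_ext,
                 params$il_open, params$il_ext)
}

.fold_mfe <- function(tint, params, forced) {
  fold_mfe_cpp(tint, params$stacks, params$hairpin_open, params$hairpin_ext,
               params$bulge_open, params$bulge_ext, params$il_open,
               params$il_ext, params$ml_open, params$ml_branch,
               params$ml_unpaired, forced)
}

#' Free-energy cost of opening the target site
#'
#' `dG_open` is the difference between the window's intramolecular MFE with
#' the site nucleotides forced unpaired and its unconstrained MFE.  Because
#' the constrained structure space is a subset of the unconstrained one, the
#' value is always >= 0.
#'
#' @param window A window list from [extract_window()], or a plain sequence
#'   (then `site_start`/`site_end` must be given, 0-based half-open).
#' @param params An [energy_params()] set.
#' @param site_start,site_end Site span override.
#' @return Opening cost in kcal/mol (>= 0).
#' @export
opening_energy <- function(window, params = energy_params(),
                           site_start = NULL, site_end = NULL) {
  stopifnot(inherits(params, "energy_params"))
  if (is.list(window)) {
    if (is.null(site_start)) site_start <- window$site_start
    if (is.null(site_end)) site_end <- window$site_end
  }
  seq <- normalize_sequence(.window_seq(window), what = "window")
  tint <- .encode_nt(seq)
  n <- length(tint)
  stopifnot(site_start >= 0L, site_end > site_start, site_end <= n)
  forced <- rep(FALSE, n)
  forced[(site_start + 1L):site_end] <- TRUE
  .fold_mfe(tint, params, forced) - .fold_mfe(tint, params, rep(FALSE, n))
}

#' Assemble the per-site energy triple
#'
#' @inheritParams duplex_energy
#' @return A list with `dG_duplex`, `dG_open` and `ddG = dG_duplex - dG_open`
#'   (all kcal/mol).
#' @export
site_energies <- function(mirna, window, params = energy_params()) {
  dg_duplex <- duplex_energy(mirna, window, params)
  dg_open <- opening_energy(window, params)
  list(dG_duplex = dg_duplex, dG_open = dg_open, ddG = dg_duplex - dg_open)
}
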