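# Independent brute-force oracles used to cross-check the scanner and the
# energy dynamic programs.  These deliberately share no code with the
# package internals: per-position string comparisons for the scanner,
# explicit structure enumeration with a loop-decomposition evaluator for the
# energies.

rand_rna <- function(n, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# -- seed-match oracle -------------------------------------------------------

oracle_pair_class <- function(m, t) {
  if ((m == "A" && t == "U") || (m == "U" && t == "A") ||
      (m == "G" && t == "C") || (m == "C" && t == "G")) return("wc")
  if ((m == "G" && t == "U") || (m == "U" && t == "G")) return("gu")
  "none"
}

oracle_classify <- function(mirna, frame8) {
  m <- strsplit(mirna, "")[[1L]][1:8]
  f <- strsplit(frame8, "")[[1L]]
  cls <- vapply(1:8, function(p) oracle_pair_class(m[p], f[9L - p]), "")
  a1 <- f[8L] == "A"
  if (all(cls[2:8] == "wc") && a1) return(list(type = "2t8A1", wob = NA_integer_))
  if (all(cls[2:8] == "wc")) return(list(type = "2t8", wob = NA_integer_))
  if (all(cls[2:7] == "wc") && a1) return(list(type = "2t7A1", wob = NA_integer_))
  if (all(cls[2:7] == "wc")) return(list(type = "2t7", wob = NA_integer_))
  if (all(cls != "none") && sum(cls == "gu") == 1L) {
    return(list(type = "1t8GU", wob = which(cls == "gu")))
  }
  NULL
}

# site span per type, as (offset from frame start, length)
.ORACLE_SPAN <- list(`2t8A1` = c(0L, 8L), `2t8` = c(0L, 7L),
                     `2t7A1` = c(1L, 7L), `2t7` = c(1L, 6L),
                     `1t8GU` = c(0L, 8L))

oracle_scan_region <- function(mirna, region_seq) {
  L <- nchar(region_seq)
  rows <- list()
  if (L >= 8L) {
    for (s0 in 0:(L - 8L)) {
      hit <- oracle_classify(mirna, substr(region_seq, s0 + 1L, s0 + 8L))
      if (is.null(hit)) next
      span <- .ORACLE_SPAN[[hit$type]]
      rows[[length(rows) + 1L]] <- data.frame(
        start = s0 + span[1L], end = s0 + span[1L] + span[2L],
        seed_type = hit$type, wobble_pos = hit$wob, stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else data.frame(
    start = integer(), end = integer(), seed_type = character(),
    wobble_pos = integer(), stringsAsFactors = FALSE)
}

# -- duplex enumeration oracle ----------------------------------------------

.ORACLE_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

oracle_duplex <- function(mirna, target, params) {
  m <- strsplit(mirna, "")[[1L]]
  t <- strsplit(target, "")[[1L]]
  best <- 0
  recur <- function(i_prev, j_prev, pt_prev, acc) {
    if (i_prev + 1L > length(m)) return()
    for (i in (i_prev + 1L):length(m)) {
      if (j_prev - 1L < 1L) next
      for (j in (j_prev - 1L):1L) {
        p <- paste0(m[i], t[j])
        if (!p %in% .ORACLE_PAIRS) next
        a <- i - i_prev - 1L
        b <- j_prev - j - 1L
        term <- if (is.null(pt_prev)) 0
        else if (a == 0L && b == 0L) params$stacks[pt_prev, p]
        else if (a == 0L || b == 0L) params$bulge_open + params$bulge_ext * (a + b)
        else params$il_open + params$il_ext * (a + b)
        e <- acc + term
        if (e < best) best <<- e
        recur(i, j, p, e)
      }
    }
  }
  recur(0L, length(t) + 1L, NULL, params$duplex_init)
  best
}

# -- folding enumeration oracle ---------------------------------------------

# all non-crossing pair sets (min hairpin loop 3) on s[i..j], as k x 2
# matrices of 1-based positions; memoized on (i, j)
oracle_structures <- function(chars, i, j, memo = new.env(parent = emptyenv())) {
  if (j - i < 4L) return(list(matrix(integer(), ncol = 2L)))
  key <- paste(i, j)
  if (!is.null(memo[[key]])) return(memo[[key]])
  out <- oracle_structures(chars, i + 1L, j, memo)
  for (k in (i + 4L):j) {
    if (!paste0(chars[i], chars[k]) %in% .ORACLE_PAIRS) next
    inner <- oracle_structures(chars, i + 1L, k - 1L, memo)
    outer <- oracle_structures(chars, k + 1L, j, memo)
    for (si in inner) for (so in outer) {
      out[[length(out) + 1L]] <- rbind(c(i, k), si, so)
    }
  }
  memo[[key]] <- out
  out
}

# energy of one structure by loop decomposition
oracle_fold_energy <- function(chars, pairs, params) {
  if (nrow(pairs) == 0L) return(0)
  np <- nrow(pairs)
  energy <- 0
  for (k in seq_len(np)) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    # children: pairs directly enclosed by (i, j)
    enclosed <- which(pairs[, 1L] > i & pairs[, 2L] < j)
    children <- enclosed[vapply(enclosed, function(e) {
      !any(pairs[enclosed, 1L] < pairs[e, 1L] & pairs[enclosed, 2L] > pairs[e, 2L])
    }, logical(1L))]
    if (length(children) == 0L) {
      energy <- energy + params$hairpin_open + params$hairpin_ext * (j - i - 1L)
    } else if (length(children) == 1L) {
      p <- pairs[children, 1L]; q <- pairs[children, 2L]
      a <- p - i - 1L; b <- j - q - 1L
      energy <- energy + if (a == 0L && b == 0L) {
        params$stacks[paste0(chars[i], chars[j]), paste0(chars[p], chars[q])]
      } else if (a == 0L || b == 0L) {
        params$bulge_open + params$bulge_ext * (a + b)
      } else {
        params$il_open + params$il_ext * (a + b)
      }
    } else {
      unpaired <- (j - i - 1L) -
        sum(pairs[children, 2L] - pairs[children, 1L] + 1L)
      energy <- energy + params$ml_open +
        params$ml_branch * (length(children) + 1L) +
        params$ml_unpaired * unpaired
    }
  }
  energy
}

# unconstrained MFE and opening cost for a site span (0-based half-open),
# from one exhaustive enumeration
oracle_fold <- function(window, params, site_start = NULL, site_end = NULL) {
  chars <- strsplit(window, "")[[1L]]
  n <- length(chars)
  structs <- oracle_structures(chars, 1L, n)
  mfe <- 0
  mfe_constrained <- 0
  site <- if (is.null(site_start)) integer() else (site_start + 1L):site_end
  for (st in structs) {
    e <- oracle_fold_energy(chars, st, params)
    if (e < mfe) mfe <- e
    if (!any(st %in% site) && e < mfe_constrained) mfe_constrained <- e
  }
  list(mfe = mfe, dG_open = mfe_constrained - mfe)
}

# strip bookkeeping attributes from a count matrix for comparisons
count_mat <- function(x) {
  x <- unclass(x)
  attributes(x) <- attributes(x)[c("dim", "dimnames")]
  x
}
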