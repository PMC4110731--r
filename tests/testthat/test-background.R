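test_that("shuffling conserves composition and is seed-deterministic", {
  expect_identical(shuffle_sequence("AAAA", 1L), "AAAA")
  set.seed(21)
  for (k in 1:25) {
    s <- rand_rna(sample(2:120, 1L))
    seed <- sample.int(1e6, 1L)
    a <- shuffle_sequence(s, seed)
    expect_identical(sort(strsplit(a, "")[[1L]]), sort(strsplit(s, "")[[1L]]))
    expect_identical(a, shuffle_sequence(s, seed))
  }
  # shuffling must not consume the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(shuffle_sequence("ACGUACGUA", 3L)); after <- runif(1)
  expect_identical(before, after)
})

test_that("dinucleotide shuffling preserves dinucleotide counts", {
  dinuc <- function(s) {
    ch <- strsplit(s, "")[[1L]]
    table(paste0(ch[-length(ch)], ch[-1L]))
  }
  set.seed(4)
  for (k in 1:15) {
    s <- rand_rna(sample(10:80, 1L))
    a <- shuffle_sequence(s, k, method = "dinucleotide")
    expect_identical(dinuc(a), dinuc(s))
    expect_identical(a, shuffle_sequence(s, k, method = "dinucleotide"))
  }
})

test_that("match counting is per site, additive, and matches a recount", {
  mir <- c(m1 = "UGGCAUGCAAUGCUAAGCUAAA")
  genes <- list(g1 = gene_regions(utr3 = "AAGCAUGCCAAA"))
  pairs <- data.frame(mirna_id = "m1", gene_id = "g1")
  cm <- count_matches(pairs, mir, genes)
  expect_identical(attr(cm, "n_pairs"), 1L)
  expect_identical(unname(cm["2t8A1", "3utr"]), 1)
  expect_identical(sum(cm), 1)

  expect_identical(count_mat(count_matches(rbind(pairs, pairs), mir, genes)),
                   2 * count_mat(cm))

  # random corpus equals an independent per-offset oracle recount
  set.seed(12)
  mirnas <- stats::setNames(vapply(1:3, function(i) rand_rna(22), ""),
                            c("a", "b", "c"))
  genes <- lapply(1:6, function(i) {
    gene_regions(promoter = rand_rna(120), utr5 = rand_rna(80),
                 cds = rand_rna(150), utr3 = rand_rna(150))
  })
  names(genes) <- sprintf("g%d", 1:6)
  pairs <- data.frame(mirna_id = rep(c("a", "b", "c"), 2), gene_id = names(genes))
  cm <- count_matches(pairs, mirnas, genes)
  oracle <- matrix(0, 5, 4, dimnames = dimnames(cm))
  for (k in seq_len(nrow(pairs))) {
    g <- genes[[pairs$gene_id[k]]]
    for (r in names(g)) {
      o <- oracle_scan_region(mirnas[[pairs$mirna_id[k]]], g[[r]])
      for (tt in o$seed_type) oracle[tt, r] <- oracle[tt, r] + 1
    }
  }
  expect_identical(count_mat(cm), oracle)
})

test_that("shuffle background equals observed for composition-degenerate input", {
  mir <- c(m1 = "UGGCAUGCAAUGCUAAGCUAAA")
  genes <- list(g1 = gene_regions(utr3 = strrep("A", 100)))
  pairs <- data.frame(mirna_id = "m1", gene_id = "g1")
  obs <- count_matches(pairs, mir, genes)
  bg <- shuffle_background(pairs, mir, genes, n_shuffles = 3L, seed = 1L)
  expect_identical(count_mat(bg), count_mat(obs))
  bg1 <- shuffle_background(pairs, mir, genes, n_shuffles = 1L, seed = 1L)
  expect_identical(attr(bg1, "n_shuffles"), 1L)
})

test_that("shuffle background does not depend on pair iteration order", {
  set.seed(3)
  mirnas <- stats::setNames(vapply(1:2, function(i) rand_rna(22), ""), c("a", "b"))
  genes <- lapply(1:4, function(i) gene_regions(cds = rand_rna(120),
                                                utr3 = rand_rna(120)))
  names(genes) <- sprintf("g%d", 1:4)
  pairs <- data.frame(mirna_id = rep(c("a", "b"), 2), gene_id = names(genes))
  bg1 <- shuffle_background(pairs, mirnas, genes, n_shuffles = 2L, seed = 5L)
  bg2 <- shuffle_background(pairs[4:1, ], mirnas, genes, n_shuffles = 2L, seed = 5L)
  expect_identical(count_mat(bg1), count_mat(bg2))
})

test_that("signal-to-noise ratios divide observed by background", {
  obs <- matrix(100, 5, 4); bg <- matrix(50, 5, 4)
  expect_true(all(signal_to_noise(obs, bg) == 2))
  # reference cell of the published corpus: 2366 sites vs 1069 expected
  obs[1, 4] <- 2366; bg[1, 4] <- 1069
  expect_equal(signal_to_noise(obs, bg)["2t8A1", "3utr"], 2366 / 1069,
               tolerance = 1e-12)
  expect_true(all(signal_to_noise(obs, obs) == 1))
  bg[2, 1] <- 0
  expect_warning(snr <- signal_to_noise(obs, bg), "zero background")
  expect_true(is.na(snr["2t8", "promoter"]))
})

test_that("weights follow (SNR - 1) / (SNR_ref - 1) with reference weight 1", {
  snr <- matrix(1, 5, 4, dimnames = list(mirtarget:::SEED_TYPES,
                                         mirtarget:::REGION_KINDS))
  snr["2t8A1", "3utr"] <- 2366 / 1069
  snr["2t8", "3utr"] <- 4103 / 2593
  wt <- compute_weights(snr)
  expect_identical(wt$weights["2t8A1", "3utr"], 1)
  expect_equal(round(wt$weights["2t8", "3utr"], 3), 0.480)
  expect_identical(unname(wt$weights["2t7", "cds"]), 0)  # SNR 1 -> weight 0

  snr["2t7", "promoter"] <- 0.8
  expect_warning(wt2 <- compute_weights(snr), "clamped")
  expect_identical(unname(wt2$weights["2t7", "promoter"]), 0)

  snr["2t8A1", "3utr"] <- 0.9
  expect_error(compute_weights(snr), "must exceed 1")
})

test_that("weights are invariant under common rescaling of both count matrices", {
  set.seed(6)
  obs <- matrix(rpois(20, 400) + 50, 5, 4)
  bg <- matrix(rpois(20, 300) + 50, 5, 4)
  obs[1, 4] <- 4 * bg[1, 4]  # make the reference cell dominate
  w1 <- compute_weights(signal_to_noise(obs, bg))$weights
  w2 <- compute_weights(signal_to_noise(obs * 3.7, bg * 3.7))$weights
  expect_equal(w1, w2, tolerance = 1e-12)
})

test_that("per-region type proportions are row-stochastic", {
  m <- matrix(0, 5, 4)
  m[3, 2] <- 17
  expect_warning(p <- region_proportions(m), "zero total")
  expect_identical(unname(p["5utr", "2t7A1"]), 1)
  expect_true(all(is.na(p["promoter", ])))
  m[] <- 7
  p <- region_proportions(m)
  expect_true(all(p == 0.2))
  expect_equal(unname(rowSums(p)), rep(1, 4))
})

test_that("weight tables survive a TSV round trip", {
  wt <- published_weights()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_weight_table(wt, f, observed = attr(wt, "observed"),
                     background = attr(wt, "background"))
  back <- read_weight_table(f)
  expect_equal(back$weights, wt$weights, tolerance = 1e-6)
  expect_identical(back$reference, wt$reference)
  expect_error(read_weight_table(file.path(tempdir(), "nope.tsv")), "not found")
})
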