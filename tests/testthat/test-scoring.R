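# A weight table with round numbers: reference SNR 2 makes the weight of a
# cell with SNR 1 + w exactly w.
make_weights <- function(cells) {
  snr <- matrix(1, 5, 4, dimnames = list(mirtarget:::SEED_TYPES,
                                         mirtarget:::REGION_KINDS))
  snr["2t8A1", "3utr"] <- 2
  for (k in seq_len(nrow(cells))) {
    snr[cells$seed_type[k], cells$region[k]] <- 1 + cells$weight[k]
  }
  compute_weights(snr)
}

site_row <- function(seed_type, region, dG_duplex, ddG) {
  data.frame(seed_type = seed_type, region = region,
             dG_duplex = dG_duplex, ddG = ddG, stringsAsFactors = FALSE)
}

test_that("pair scores are weighted sums over the site breakdown", {
  wt <- make_weights(data.frame(seed_type = c("2t8", "2t7"),
                                region = c("3utr", "cds"),
                                weight = c(0.480, 0.068)))
  empty <- score_pair(site_row(character(), character(), numeric(), numeric()), wt)
  expect_identical(c(empty$total_dG_duplex, empty$total_ddG), c(0, 0))
  expect_identical(empty$n_sites, 0L)

  one <- score_pair(site_row("2t8A1", "3utr", -20, -12), wt)
  expect_identical(c(one$total_dG_duplex, one$total_ddG), c(-20, -12))

  two <- score_pair(rbind(site_row("2t8", "3utr", -10, -10),
                          site_row("2t7", "cds", -10, -10)), wt)
  expect_equal(two$total_dG_duplex, -5.48, tolerance = 1e-12)
  expect_equal(two$total_ddG, -5.48, tolerance = 1e-12)
  expect_identical(two$n_sites, 2L)
  expect_equal(sum(two$breakdown$weight * two$breakdown$dG_duplex),
               two$total_dG_duplex, tolerance = 1e-12)
})

test_that("a site in an undefined weight cell is an error naming the cell", {
  wt <- make_weights(data.frame(seed_type = character(), region = character(),
                                weight = numeric()))
  wt$weights["2t7", "promoter"] <- NA_real_
  expect_error(score_pair(site_row("2t7", "promoter", -5, -5), wt),
               "\\(2t7, promoter\\)")
})

test_that("duplicating a site exactly doubles its contribution", {
  set.seed(9)
  wt <- published_weights()
  for (k in 1:10) {
    st <- sample(mirtarget:::SEED_TYPES, 1)
    rg <- sample(mirtarget:::REGION_KINDS, 1)
    s1 <- site_row(st, rg, -runif(1, 5, 25), -runif(1, 5, 25))
    a <- score_pair(s1, wt)
    b <- score_pair(rbind(s1, s1), wt)
    expect_equal(b$total_dG_duplex, 2 * a$total_dG_duplex, tolerance = 1e-12)
    expect_equal(b$total_ddG, 2 * a$total_ddG, tolerance = 1e-12)
  }
})

test_that("target calls require both totals strictly below their cutoffs", {
  cut <- cutoff_preset("default")
  expect_identical(c(cut$dG_duplex, cut$ddG), c(-15, -10))
  wt <- make_weights(data.frame(seed_type = character(), region = character(),
                                weight = numeric()))
  score <- function(dup, ddg) {
    s <- score_pair(site_row("2t8A1", "3utr", dup, ddg), wt)
    call_target(s, cut)
  }
  expect_true(score(-20, -12))
  expect_false(score(-20, -9))   # second criterion fails
  expect_false(score(-14, -12))  # first criterion fails
  expect_false(score(-15, -10))  # boundary equality is a non-call
  empty <- score_pair(site_row(character(), character(), numeric(), numeric()), wt)
  expect_false(call_target(empty, cut))
  expect_identical(c(cutoff_preset("stringent")$dG_duplex,
                     cutoff_preset("stringent")$ddG), c(-25, -14))
  expect_warning(cutoffs(5, -1), "positive")
})

test_that("adding a stabilizing weighted site never revokes a call", {
  set.seed(18)
  wt <- published_weights()
  cut <- cutoff_preset("default")
  for (k in 1:20) {
    base <- site_row(sample(mirtarget:::SEED_TYPES, 3, replace = TRUE),
                     sample(mirtarget:::REGION_KINDS, 3, replace = TRUE),
                     -runif(3, 0, 30), -runif(3, 0, 30))
    extra <- site_row("2t8A1", "3utr", -runif(1, 0, 10), -runif(1, 0, 10))
    before <- score_pair(base, wt)
    after <- score_pair(rbind(base, extra), wt)
    expect_lte(after$total_dG_duplex, before$total_dG_duplex)
    expect_lte(after$total_ddG, before$total_ddG)
    if (call_target(before, cut)) expect_true(call_target(after, cut))
  }
})

test_that("predictions rank by ddG, then duplex energy, then gene id", {
  df <- data.frame(mirna_id = "m", gene_id = c("g3", "g1", "g2", "g4"),
                   total_dG_duplex = c(-5, -20, -10, -20),
                   total_ddG = c(-12, -30, -12, -30),
                   stringsAsFactors = FALSE)
  r <- rank_predictions(df)
  expect_identical(r$gene_id, c("g1", "g4", "g2", "g3"))
  expect_identical(nrow(rank_predictions(df[0, ])), 0L)
})

test_that("the end-to-end pipeline scores pairs and honors containment", {
  corpus <- generate_corpus(synth_spec(
    n_mirnas = 2, n_genes = 8,
    planted = data.frame(seed_type = c("2t8A1", "2t8"),
                         region = c("3utr", "cds"), count = c(1, 1)),
    enrichment_factor = 2, seed = 31))
  wt <- published_weights()
  res <- predict_targets(corpus$mirnas, corpus$genes, wt, pairs = corpus$pairs,
                         details = TRUE)
  expect_identical(nrow(res$scores), nrow(corpus$pairs))
  expect_true(all(res$scores$n_sites >= 2))  # at least the planted sites
  expect_equal(res$scores$total_ddG,
               res$scores$total_ddG[order(res$scores$total_ddG)],
               tolerance = 1e-12)
  # stringent calls are a subset of default calls on the same corpus
  def <- call_target(res$scores, cutoff_preset("default"))
  str <- call_target(res$scores, cutoff_preset("stringent"))
  expect_true(all(!str | def))
})
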