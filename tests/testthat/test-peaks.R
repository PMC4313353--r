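rep_peaks <- function(start, end, replicate, fold = 5, species = "s") {
  data.table::data.table(species = species, chrom = "chr1", start = start,
                         end = end, replicate = replicate,
                         fold_enrichment = fold)
}

test_that("build_consensus merges reciprocally overlapping replicate peaks", {
  pk <- rep_peaks(c(100, 150), c(300, 350), c(1, 2), fold = c(4, 6))
  cs <- build_consensus(pk)
  expect_equal(nrow(cs), 1)
  expect_equal(cs$start, 100)
  expect_equal(cs$end, 350)
  expect_equal(cs$intensity, 5)
  expect_equal(cs$reproducibility, 1)
})

test_that("build_consensus discards non-reproducible peaks", {
  pk <- rep_peaks(c(0, 190), c(200, 400), c(1, 2))
  expect_equal(nrow(build_consensus(pk)), 0)
  # single replicate without the relaxation flag
  one <- rep_peaks(10, 100, 1)
  expect_warning(res <- build_consensus(one), "exceeds available replicates")
  expect_equal(nrow(res), 0)
})

test_that("single-replicate relaxation retains all peaks verbatim", {
  one <- rep_peaks(c(10, 500), c(100, 900), c(1, 1), fold = c(2, 3))
  res <- build_consensus(one, single_replicate_ok = TRUE)
  expect_equal(res$start, c(10, 500))
  expect_equal(res$end, c(100, 900))
  expect_equal(res$intensity, c(2, 3))
  expect_equal(res$reproducibility, c(1, 1))
})

test_that("consensus matches the brute-force oracle on random replicate sets", {
  set.seed(21)
  for (k in 1:150) {
    n <- sample(2:8, 1)
    s <- sample(seq(0, 400, 10), n, replace = TRUE)
    pk <- rep_peaks(s, s + sample(seq(40, 200, 10), n, replace = TRUE),
                    sample(1:3, n, replace = TRUE),
                    fold = round(runif(n, 1, 9), 2))
    cs <- suppressWarnings(build_consensus(pk))
    oc <- oracle_consensus(pk)
    expect_equal(nrow(cs), nrow(oc))
    if (nrow(oc)) {
      expect_equal(cs$start, oc$start)
      expect_equal(cs$end, oc$end)
      expect_equal(cs$intensity, oc$intensity)
      expect_equal(cs$n_replicates, oc$n_replicates)
    }
  }
})

test_that("consensus counts are robust across overlap thresholds", {
  # replicate peaks of one element overlap near-completely, so the threshold
  # hardly matters under realistic noise: counts vary by < 10% from 0.1 to 0.8
  w <- simulate_world(small_world_config(seed = 22))
  pk <- world_peaks(w, "human", "H3K27ac")
  counts <- vapply(c(0.1, 0.3, 0.5, 0.8),
                   function(mo) nrow(build_consensus(pk, min_overlap = mo)),
                   numeric(1))
  expect_lt((max(counts) - min(counts)) / max(counts), 0.1)
  # the reproducible peak support itself shrinks monotonically: a consensus
  # region found at a high threshold is covered by one at any lower threshold
  cs_hi <- build_consensus(pk, min_overlap = 0.8)
  cs_lo <- build_consensus(pk, min_overlap = 0.2)
  ov <- interval_overlaps(cs_hi, cs_lo)
  expect_setequal(unique(ov$i), seq_len(nrow(cs_hi)))
})

test_that("classify_elements merges dual-marked regions and partitions the rest", {
  k4 <- build_consensus(rep_peaks(c(1000, 1010), c(2000, 1990), 1:2))
  k27 <- build_consensus(rep_peaks(c(1400, 1410), c(2600, 2590), 1:2))
  el <- classify_elements(k4, k27)
  expect_equal(el$class, "promoter_dual")
  expect_equal(el$start, 1000)
  expect_equal(el$end, 2600)

  # 10% of K4 / ~5% of K27: two separate elements
  k4b <- build_consensus(rep_peaks(c(0, 0), c(1000, 1000), 1:2))
  k27b <- build_consensus(rep_peaks(c(900, 900), c(3000, 3000), 1:2))
  el2 <- classify_elements(k4b, k27b)
  expect_setequal(el2$class, c("promoter_k4", "enhancer"))

  # lone K27 far away
  el3 <- classify_elements(k4b[0], build_consensus(rep_peaks(c(5000, 5000), c(7000, 7000), 1:2)))
  expect_equal(el3$class, "enhancer")
  expect_equal(el3$start, 5000)
  expect_equal(el3$end, 7000)
})

test_that("classification partitions every consensus peak exactly once", {
  set.seed(23)
  for (k in 1:20) {
    n <- 10
    s4 <- sample(seq(0, 5000, 100), n)
    s27 <- sample(seq(0, 5000, 100), n)
    k4 <- build_consensus(rep_peaks(rep(s4, 2), rep(s4 + 400, 2), rep(1:2, each = n)))
    k27 <- build_consensus(rep_peaks(rep(s27, 2), rep(s27 + 600, 2), rep(1:2, each = n)))
    el <- classify_elements(k4, k27)
    n_dual <- sum(el$class == "promoter_dual")
    # each class-dual element consumes >= 1 K4 and >= 1 K27 consensus peak
    expect_equal(sum(el$class == "promoter_k4") +
                   sum(el$class == "enhancer") + 2 * n_dual <= nrow(k4) + nrow(k27), TRUE)
    expect_true(all(table(el$class) >= 0))
    # total span coverage: every consensus peak lies inside some element
    cov4 <- interval_overlaps(k4, el)
    expect_setequal(unique(cov4$i), seq_len(nrow(k4)))
  }
})

test_that("element_intensity is the mean fold enrichment", {
  expect_equal(element_intensity(c(4, 6)), 5)
  expect_equal(element_intensity(7.3), 7.3)
  expect_equal(element_intensity(c(2, 3, 10)), 5)
  expect_error(element_intensity(numeric()), "empty")
})

test_that("noise-free consensus equals the true element set", {
  cfg <- noise_free(small_world_config(seed = 31))
  w <- simulate_world(cfg)
  cons <- consensus_all(w)
  for (sp in c("human", "mouse", "opossum")) {
    el <- cons[[sp]]$elements
    truth <- w$state[, sp]
    expect_equal(nrow(el), sum(truth > 0))
    cls_true <- c("promoter_dual", "promoter_k4", "enhancer")[truth[truth > 0]]
    for (cl in unique(cls_true)) {
      expect_equal(sum(el$class == cl), sum(cls_true == cl))
    }
    # spans equal the true element intervals
    lay <- w$layouts[[sp]]
    act <- which(truth > 0)
    st <- lay$start[match(w$elements$block_id[act], lay$block_id)] +
      w$elements$offset[act]
    expect_setequal(el$start, st)
  }
})
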