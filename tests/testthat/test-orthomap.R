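two_block_map <- function() {
  ortho_map(data.table::data.table(
    species_a = "A", chrom_a = "chr1",
    start_a = c(1000, 5000), end_a = c(3000, 7000), strand_a = "+",
    species_b = "B", chrom_b = c("chr1", "chr2"),
    start_b = c(100, 9000), end_b = c(2100, 11000), strand_b = "+"))
}

test_that("projection is affine within a block", {
  m <- two_block_map()
  r <- iv(1500, 1800, species = "A")
  p <- project(r, m)
  expect_equal(p$status, "unique")
  expect_equal(p$target$chrom, "chr1")
  expect_equal(p$target$start, 100 + 500)
  expect_equal(p$target$end, 100 + 800)
})

test_that("unmapped and split projections are recognised", {
  m <- two_block_map()
  expect_equal(project(iv(3500, 4000, species = "A"), m)$status, "unmapped")
  # spans two blocks whose targets lie on different chromosomes
  expect_equal(project(iv(2500, 5500, species = "A"), m)$status, "split")
})

test_that("a large internal gap splits, a small one stays unique", {
  mk <- function(gap) ortho_map(data.table::data.table(
    species_a = "A", chrom_a = "chr1",
    start_a = c(0, 1100), end_a = c(1000, 2100), strand_a = "+",
    species_b = "B", chrom_b = "chr1",
    start_b = c(0, 1000 + gap), end_b = c(1000, 2000 + gap), strand_b = "+"))
  r <- iv(500, 1600, species = "A")   # 1100 bp over both blocks
  small <- project(r, mk(100))
  expect_equal(small$status, "unique")
  big <- project(r, mk(50000))
  expect_equal(big$status, "split")
})

test_that("minus-strand blocks project reversed", {
  m <- ortho_map(data.table::data.table(
    species_a = "A", chrom_a = "chr1", start_a = 100, end_a = 200, strand_a = "+",
    species_b = "B", chrom_b = "chr1", start_b = 1000, end_b = 1100, strand_b = "-"))
  p <- project(iv(100, 120, species = "A"), m)
  expect_equal(p$status, "unique")
  expect_equal(p$target$start, 1080)
  expect_equal(p$target$end, 1100)
})

test_that("malformed maps are rejected at load", {
  bad <- data.table::data.table(
    species_a = "A", chrom_a = "chr1", start_a = c(0, 500), end_a = c(1000, 1500),
    strand_a = "+", species_b = "B", chrom_b = "chr1",
    start_b = c(0, 5000), end_b = c(1000, 6000), strand_b = "+")
  expect_error(ortho_map(bad), "overlapping blocks")
  uneq <- data.table::data.table(
    species_a = "A", chrom_a = "chr1", start_a = 0, end_a = 1000, strand_a = "+",
    species_b = "B", chrom_b = "chr1", start_b = 0, end_b = 900, strand_b = "+")
  expect_error(ortho_map(uneq), "equal lengths")
})

test_that("orthology map TSVs round-trip", {
  m <- two_block_map()
  f <- tempfile(fileext = ".tsv")
  write_ortho_map(m, f)
  m2 <- read_ortho_map(f)
  expect_equal(as.data.frame(m2), as.data.frame(m))
})

test_that("conservation calls follow the 50%-of-projection rule", {
  proj <- data.table::data.table(status = "unique", chrom = "chr1",
                                 start = 1000, end = 1500)
  tg <- iv(1200, 2000, species = "B")
  expect_equal(call_conservation(proj, tg, "B"), "conserved")   # 300/500
  tg2 <- iv(1450, 3000, species = "B")
  expect_equal(call_conservation(proj, tg2, "B"), "absent")     # 50/500
  split_proj <- data.table::data.table(status = "split", chrom = NA_character_,
                                       start = NA_real_, end = NA_real_)
  expect_equal(call_conservation(split_proj, tg, "B"), "unalignable")
})

test_that("conservation is monotone in the overlap threshold", {
  set.seed(41)
  for (k in 1:25) {
    pr <- data.table::data.table(status = "unique", chrom = "chr1",
                                 start = s <- sample(0:500, 8), end = s + 100)
    tg <- iv(sample(0:500, 5), 0, species = "B")
    tg$end <- tg$start + sample(50:250, 5, replace = TRUE)
    prev <- NULL
    for (mo in c(0.1, 0.25, 0.5, 0.75, 1)) {
      cons <- sum(conservation_calls(pr, tg, "B", mo) == "conserved")
      if (!is.null(prev)) expect_lte(cons, prev)
      prev <- cons
    }
  }
})

test_that("projection round-trips through a world's reciprocal maps", {
  w <- simulate_world(noise_free(small_world_config(seed = 33)))
  ab <- orthology_map(w, "human", "mouse")
  ba <- orthology_map(w, "mouse", "human")
  act <- which(w$active[, "human"] & w$block_presence[match(w$elements$block_id,
                                                            w$blocks$block_id), "mouse"])
  act <- head(act, 50)
  lay <- w$layouts$human
  st <- lay$start[match(w$elements$block_id[act], lay$block_id)] + w$elements$offset[act]
  q <- iv(st, st + w$elements$length[act], species = "human")
  p1 <- project_intervals(q, ab)
  expect_true(all(p1$status == "unique"))
  q2 <- data.table::data.table(species = "mouse", chrom = p1$chrom,
                               start = p1$start, end = p1$end)
  p2 <- project_intervals(q2, ba)
  expect_equal(p2$start, q$start)
  expect_equal(p2$end, q$end)
})

test_that("pairwise ratios average reciprocal comparisons", {
  # constructed: A->B 60/100 conserved, B->A 40/100
  blocks <- data.table::data.table(
    species_a = "A", chrom_a = "chr1",
    start_a = seq(0, 99) * 1000, end_a = seq(0, 99) * 1000 + 500, strand_a = "+",
    species_b = "B", chrom_b = "chr1",
    start_b = seq(0, 99) * 1000, end_b = seq(0, 99) * 1000 + 500, strand_b = "+")
  m_ab <- ortho_map(blocks)
  m_ba <- flip_map(m_ab)
  mk_el <- function(sp, rows) {
    data.table::data.table(species = sp, chrom = "chr1",
                           start = (rows - 1) * 1000, end = (rows - 1) * 1000 + 500,
                           name = paste0(sp, rows), class = "enhancer")
  }
  els_a <- mk_el("A", 1:100)
  els_b <- mk_el("B", 1:100)
  t_b <- list(k4 = els_b[0], k27 = mk_el("B", 1:60))
  t_a <- list(k4 = els_a[0], k27 = mk_el("A", 1:40))
  pr <- pairwise_conservation_ratio(els_a, els_b, m_ab, m_ba, t_a, t_b)
  expect_equal(pr$ratio_ab, 0.6)
  expect_equal(pr$ratio_ba, 0.4)
  expect_equal(pr$ratio, 0.5)
})

test_that("no-loss world gives pairwise ratios near 1", {
  cfg <- noise_free(small_world_config(
    seed = 34,
    classes = data.frame(class = c("promoter_dual", "enhancer"),
                         n_root = c(150L, 300L), half_life = Inf,
                         birth_rate = 0, frac_young = 0)))
  w <- simulate_world(cfg)
  cons <- consensus_all(w)
  m <- conservation_ratio_matrices(w, cons, species = c("human", "mouse", "opossum"))
  for (g in names(m)) {
    off <- m[[g]][upper.tri(m[[g]])]
    expect_true(all(off > 0.99))
  }
})

test_that("coverage false-negative fraction uses the control tail", {
  set.seed(42)
  ctrl <- rnorm(20000, 10, 1)
  expect_equal(coverage_false_negative_fraction(rnorm(20000, 10, 1), ctrl),
               0.025, tolerance = 3 * sqrt(0.025 * 0.975 / 20000) / 0.025)
  expect_equal(coverage_false_negative_fraction(rep(5, 10), ctrl), 0)
  expect_equal(coverage_false_negative_fraction(rep(10 + 10 * 1, 10), ctrl), 1)
})
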