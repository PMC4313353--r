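mk_states <- function(m) {
  # m: list of per-species state vectors
  do.call(cbind, m)
}

test_that("highly conserved requires enrichment in every required species", {
  el <- data.table::data.table(species = "human", chrom = "chr1",
                               start = c(0, 1000, 2000) * 10,
                               end = c(0, 1000, 2000) * 10 + 500,
                               name = c("e1", "e2", "e3"),
                               class = c("promoter_dual", "enhancer", "promoter_dual"))
  panel <- species_panel("human", c("s1", "s2", "s3"))
  states <- mk_states(list(
    s1 = c("dual", "k27_only", "dual"),
    s2 = c("dual", "none", "dual"),
    s3 = c("dual", "k27_only", "unalignable")))
  rownames(states) <- el$name
  hc <- find_highly_conserved(el, states, panel)
  expect_equal(hc$name, "e1")     # e2 fails s2, e3 unalignable in s3
  expect_equal(hc$assigned_class, "promoter")
  expect_equal(hc$n_support, 3)
})

test_that("majority rule classifies and ties break to promoter", {
  expect_equal(classify_majority(c(rep("dual", 8), rep("k27_only", 2))), "promoter")
  expect_equal(classify_majority(c("dual", rep("k27_only", 9))), "enhancer")
  expect_equal(classify_majority(c(rep("dual", 5), rep("k27_only", 5))), "promoter")
  expect_equal(classify_majority(c("none", "k4_only")), "promoter")
  expect_error(classify_majority(c("none", "unalignable")), "cannot classify")
})

test_that("enlarging the required panel never grows the highly conserved set", {
  set.seed(61)
  el <- data.table::data.table(species = "human", chrom = "chr1",
                               start = (0:49) * 1000, end = (0:49) * 1000 + 500,
                               name = sprintf("e%02d", 1:50), class = "enhancer")
  sps <- paste0("s", 1:6)
  states <- matrix(sample(c("dual", "k27_only", "none", "unalignable"), 300,
                          replace = TRUE, prob = c(0.3, 0.4, 0.2, 0.1)),
                   50, 6, dimnames = list(el$name, sps))
  prev <- Inf
  for (k in 2:6) {
    hc <- find_highly_conserved(el, states, species_panel("human", sps[1:k]))
    expect_lte(nrow(hc), prev)
    prev <- nrow(hc)
  }
})

test_that("permutation p-value handles the trivial and extreme cases", {
  sets <- list(s1 = list(H3K4me3 = letters[1:5], H3K27ac = letters[3:8]),
               s2 = list(H3K4me3 = letters[2:6], H3K27ac = letters[1:4]))
  r0 <- permutation_test_conserved_count(0, sets, letters, n_iter = 200, seed = 1)
  expect_equal(r0$p, 1)
  # observed far above anything attainable -> p = 1/(n_iter+1), labelled bound
  r1 <- permutation_test_conserved_count(26, sets, letters, n_iter = 1000, seed = 1)
  expect_equal(r1$p, 1 / 1001)
  expect_match(r1$p_label, "^< ")
})

test_that("hypergeometric sampler matches the literal permutation null", {
  universe <- sprintf("x%02d", 1:12)
  sets <- list(s1 = list(m1 = universe[1:7], m2 = universe[5:10]),
               s2 = list(m1 = universe[2:9]),
               s3 = list(m1 = universe[1:6], m2 = universe[4:11]))
  a <- permutation_test_conserved_count(5, sets, universe, n_iter = 4000,
                                        seed = 2, method = "hypergeometric")
  b <- permutation_test_conserved_count(5, sets, universe, n_iter = 4000,
                                        seed = 3, method = "permute")
  expect_equal(a$null_mean, b$null_mean, tolerance = 0.05)
  expect_equal(a$null_sd, b$null_sd, tolerance = 0.1)
  expect_equal(a$p, b$p, tolerance = 0.05)
})

test_that("lineage-specific calls respect clade membership rules", {
  el <- data.table::data.table(species = "ref", chrom = "chr1",
                               start = (0:3) * 1e4, end = (0:3) * 1e4 + 500,
                               name = paste0("e", 1:4), class = "enhancer")
  clade <- list(members = c("ref", "in1", "in2", "extra"),
                required = c("ref", "in1", "in2"), reference = "ref")
  calls <- cbind(in1 = c("conserved", "conserved", "absent", "conserved"),
                 in2 = c("conserved", "conserved", "conserved", "conserved"),
                 extra = c("absent", "conserved", "absent", "absent"),
                 out1 = c("absent", "absent", "absent", "conserved"),
                 out2 = c("unalignable", "absent", "absent", "absent"))
  states <- ifelse(calls == "conserved", "k27_only",
                   ifelse(calls == "absent", "none", "unalignable"))
  rownames(calls) <- rownames(states) <- el$name
  ls <- find_lineage_specific(el, calls, states, clade)
  # e1 in; e2 in (extra is a non-disqualifying clade member); e3 fails in1;
  # e4 conserved outside the clade
  expect_setequal(ls$name, c("e1", "e2"))
  expect_true(all(ls$assigned_class == "enhancer"))
})

test_that("recently evolved elements have no conserved call anywhere", {
  el <- data.table::data.table(species = "ref", chrom = "chr1",
                               start = (0:2) * 1e4, end = (0:2) * 1e4 + 500,
                               name = paste0("e", 1:3),
                               class = c("enhancer", "promoter_dual", "enhancer"))
  calls <- cbind(s1 = c("absent", "conserved", "unalignable"),
                 s2 = c("unalignable", "absent", "unalignable"))
  rownames(calls) <- el$name
  re <- find_recently_evolved(el, calls)
  expect_setequal(re$name, c("e1", "e3"))   # e3: unalignable everywhere counts
  expect_equal(re$assigned_class[re$name == "e1"], "enhancer")
})

test_that("conserved sets partition sensibly on a simulated world", {
  cfg <- small_world_config(seed = 62)
  w <- simulate_world(cfg)
  cons <- consensus_all(w)
  others <- setdiff(w$species, "human")
  maps <- lapply(others, function(s) orthology_map(w, "human", s))
  names(maps) <- others
  targets <- lapply(others, function(s) list(k4 = cons[[s]]$k4, k27 = cons[[s]]$k27))
  names(targets) <- others
  pr <- conservation_profile(cons$human$elements, maps, targets)
  panel <- species_panel("human", c("macaque", "marmoset", "mouse", "cow"))
  hc <- find_highly_conserved(cons$human$elements, pr$states, panel)
  re <- find_recently_evolved(cons$human$elements, pr$calls)
  expect_true(all(hc$name %in% cons$human$elements$name))
  expect_equal(length(intersect(hc$name, re$name)), 0)
})
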