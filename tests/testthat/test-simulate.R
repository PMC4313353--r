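test_that("identical config and seed give identical worlds", {
  w1 <- simulate_world(small_world_config(seed = 5))
  w2 <- simulate_world(small_world_config(seed = 5))
  expect_equal(w1$peaks, w2$peaks)
  expect_equal(w1$active, w2$active)
  expect_equal(w1$expr, w2$expr)
  w3 <- simulate_world(small_world_config(seed = 6))
  expect_false(identical(w1$peaks, w3$peaks))
})

test_that("no-loss limit keeps every root element everywhere DNA survives", {
  cfg <- noise_free(small_world_config(
    seed = 8,
    classes = data.frame(class = "enhancer", n_root = 200L, half_life = Inf,
                         birth_rate = 0, frac_young = 0),
    align_half_life = 1e9))
  w <- simulate_world(cfg)
  expect_true(all(w$active))
})

test_that("instant-loss limit shares nothing between species", {
  cfg <- small_world_config(
    seed = 9,
    classes = data.frame(class = "enhancer", n_root = 200L, half_life = 1e-6,
                         birth_rate = 0, frac_young = 0))
  w <- simulate_world(cfg)
  expect_equal(sum(w$active), 0)
})

test_that("two-taxon shared fraction follows both-lineage exponential retention", {
  tr <- ape::read.tree(text = "(A:50,B:50);")
  cfg <- sim_config(seed = 10, tree = tr, anchor = "A", n_root_blocks = 11000L,
                    classes = data.frame(class = "enhancer", n_root = 10000L,
                                         half_life = 50, birth_rate = 0,
                                         frac_young = 0),
                    align_half_life = 1e9, n_genes = 50L, n_psg = 5L)
  w <- simulate_world(cfg)
  shared <- mean(w$active[, "A"] & w$active[, "B"])
  p <- exp(-log(2))^2   # both lineages retain over one half-life
  expect_equal(shared, p, tolerance = 3 * sqrt(p * (1 - p) / 10000) / p)
})

test_that("replicate reproducibility matches the binomial closed form", {
  # sensitivity 0.8, 3 replicates: P(detected in >= 2) = 3 p^2 (1-p) + p^3
  cfg <- small_world_config(
    seed = 12, sensitivity = 0.8, sens_slope = 0, fp_rate = 0, mark_switch = 0,
    n_root_blocks = 3000L,
    classes = data.frame(class = "enhancer", n_root = 2000L, half_life = Inf,
                         birth_rate = 0, frac_young = 0))
  w <- simulate_world(cfg)
  cons <- consensus_all(w)
  p <- 0.896
  for (sp in c("human", "mouse")) {
    n_true <- sum(w$state[, sp] == 3)
    frac <- nrow(cons[[sp]]$elements) / n_true
    expect_equal(frac, p, tolerance = 3 * sqrt(p * (1 - p) / n_true) / p)
  }
})

test_that("element birth respects clade structure", {
  w <- simulate_world(small_world_config(seed = 13))
  tips <- w$species
  n_tip <- length(tips)
  cl <- regevo:::clade_tips(w$tree)
  for (k in sample(nrow(w$elements), 200)) {
    bn <- w$elements$birth_node[k]
    inside <- cl[[bn]]
    outside <- setdiff(tips, inside)
    if (length(outside)) {
      expect_false(any(w$active[k, outside]))
    }
  }
})

test_that("young DNA blocks are only alignable within their clade of birth", {
  w <- simulate_world(small_world_config(seed = 14))
  cl <- regevo:::clade_tips(w$tree)
  dv <- divergence_matrix(w$tree)
  young <- which(w$blocks$birth_age < max(regevo:::node_ages(w$tree)))
  for (k in sample(young, min(150, length(young)))) {
    pres <- w$species[w$block_presence[k, ]]
    expect_true(all(pres %in% cl[[w$blocks$birth_node[k]]]))
    if (length(pres) >= 2) {
      expect_lte(max(dv[pres, pres]), w$blocks$birth_age[k] + 1e-9)
    }
  }
})

test_that("orthologous elements occupy paired blocks in reciprocal maps", {
  w <- simulate_world(small_world_config(seed = 15))
  m <- orthology_map(w, "human", "macaque")
  # every element active in both species projects uniquely and back
  both <- which(w$active[, "human"] & w$active[, "macaque"])
  lay <- w$layouts$human
  st <- lay$start[match(w$elements$block_id[both], lay$block_id)] + w$elements$offset[both]
  pr <- project_intervals(iv(st, st + w$elements$length[both], species = "human"), m)
  expect_true(all(pr$status == "unique"))
})

test_that("emitted fixtures round-trip and are seed-deterministic", {
  w <- simulate_world(small_world_config(seed = 16))
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- emit_fixtures(w, d1)
  m2 <- emit_fixtures(simulate_world(small_world_config(seed = 16)), d2)
  expect_equal(m1$md5, m2$md5)
  pk <- load_peak_fixtures(d1)
  expect_equal(nrow(pk), nrow(w$peaks))
  expect_equal(pk$start, w$peaks$start)
  expect_equal(pk$fold_enrichment, w$peaks$fold_enrichment, tolerance = 1e-6)
  m <- read_ortho_map(file.path(d1, "maps", "human__mouse.tsv"))
  expect_equal(as.data.frame(m), as.data.frame(orthology_map(w, "human", "mouse")))
  tr <- read_species_tree(file.path(d1, "tree.nwk"))
  expect_equal(sort(tr$tip.label), sort(w$species))
})

test_that("noise-free replicate peaks equal the true element set", {
  cfg <- noise_free(small_world_config(seed = 17))
  w <- simulate_world(cfg)
  pk <- world_peaks(w, "human", "H3K27ac")
  truth <- sum(w$state[, "human"] %in% c(1L, 3L))
  expect_equal(nrow(pk), truth * w$config$n_replicates)
})
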