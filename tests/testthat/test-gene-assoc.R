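test_that("regulatory domains follow basal-plus-extension with 1 Mb caps", {
  g <- data.table::data.table(gene_id = "g1", chrom = "chr1", tss = 2e6, strand = "+")
  d <- build_regulatory_domains(g, c(chr1 = 1e7))
  expect_equal(d$basal_start, 2e6 - 5000)
  expect_equal(d$basal_end, 2e6 + 1000)
  expect_equal(d$dom_start, 2e6 - 5000 - 1e6)
  expect_equal(d$dom_end, 2e6 + 1000 + 1e6)

  gm <- data.table::data.table(gene_id = "gm", chrom = "chr1", tss = 2e6, strand = "-")
  dm <- build_regulatory_domains(gm, c(chr1 = 1e7))
  expect_equal(dm$basal_start, 2e6 - 1000)
  expect_equal(dm$basal_end, 2e6 + 5000)
})

test_that("extension stops at the neighbour's basal domain", {
  g <- data.table::data.table(gene_id = c("a", "b"), chrom = "chr1",
                              tss = c(2e6, 2.1e6), strand = "+")
  d <- build_regulatory_domains(g, c(chr1 = 1e7))
  # upstream gene's downstream extension stops at neighbour's basal start
  expect_equal(d$dom_end[d$gene_id == "a"], 2.1e6 - 5000)
  expect_equal(d$dom_start[d$gene_id == "b"], 2e6 + 1000)
})

test_that("domains are clipped to chromosome bounds with a warning", {
  g <- data.table::data.table(gene_id = "edge", chrom = "chr1", tss = 2000,
                              strand = "+")
  expect_warning(d <- build_regulatory_domains(g, c(chr1 = 5e4)), "clipped")
  expect_equal(d$basal_start, 0)
  expect_equal(d$dom_start, 0)
  expect_equal(d$dom_end, 5e4)
})

test_that("domains match the brute-force construction on random gene sets", {
  set.seed(81)
  for (k in 1:30) {
    n <- sample(2:10, 1)
    g <- data.table::data.table(gene_id = sprintf("g%02d", 1:n), chrom = "chr1",
                                tss = sort(sample(seq(5e4, 5e6, 1e3), n)),
                                strand = sample(c("+", "-"), n, TRUE))
    d <- build_regulatory_domains(g, c(chr1 = 6e6))
    d <- d[match(g$gene_id, d$gene_id)]
    for (i in seq_len(n)) {
      o <- oracle_domain(g, i, 6e6)
      expect_equal(unname(c(d$dom_start[i], d$dom_end[i])), unname(o))
    }
  }
})

test_that("element-gene links and gene-desert behaviour", {
  g <- data.table::data.table(gene_id = c("a", "b"), chrom = "chr1",
                              tss = c(1e6, 1.2e6), strand = "+")
  d <- build_regulatory_domains(g, c(chr1 = 1e8))
  # inside a's basal domain, upstream of b's extension limit (a's basal end)
  inside <- data.table::data.table(species = "s", chrom = "chr1",
                                   start = 1e6 - 4000, end = 1e6 - 3000,
                                   name = "e_in", class = "enhancer")
  spanning <- data.table::data.table(species = "s", chrom = "chr1",
                                     start = 1.2e6 - 6000, end = 1.2e6 - 3000,
                                     name = "e_span", class = "enhancer")
  desert <- data.table::data.table(species = "s", chrom = "chr1",
                                   start = 9e7, end = 9e7 + 2000,
                                   name = "e_far", class = "enhancer")
  el <- rbind(inside, spanning, desert)
  assoc <- associate_elements(el, d)
  expect_setequal(assoc$links$gene_id[assoc$links$name == "e_in"], "a")
  expect_setequal(assoc$links$gene_id[assoc$links$name == "e_span"], c("a", "b"))
  expect_equal(sum(assoc$links$name == "e_far"), 0)
})

test_that("tsps selection applies all three conditions", {
  expr <- rbind(g1 = c(liver = 30, brain = 10, heart = 10),
                g2 = c(liver = 12, brain = 10, heart = 10),
                g3 = c(liver = 100, brain = 200, heart = 10),
                g4 = c(liver = 0, brain = 0, heart = 0),
                g5 = c(liver = 9, brain = 1, heart = 1))
  ts <- tsps_and_liver_specific(expr, "liver")
  expect_equal(ts$tsps[ts$gene_id == "g1"], 3)
  expect_true(ts$selected[ts$gene_id == "g1"])
  expect_equal(ts$tsps[ts$gene_id == "g2"], 1.2)
  expect_false(ts$selected[ts$gene_id == "g2"])
  expect_false(ts$selected[ts$gene_id == "g3"])   # argmax is brain
  expect_equal(ts$tsps[ts$gene_id == "g4"], 0)
  expect_false(ts$selected[ts$gene_id == "g4"])
  expect_false(ts$selected[ts$gene_id == "g5"])   # tsps high but RPKM <= 10
})

test_that("binomial gene-set enrichment reports only strong, significant terms", {
  fg <- paste0("g", 1:50)
  bg <- paste0("g", 1:1000)
  sets <- list(hit = paste0("g", 1:20),            # 20/50 fg vs 2% bg
               null = paste0("g", seq(10, 1000, 10)))
  res <- geneset_enrichment_binomial(fg, bg, sets)
  expect_equal(res$p[res$term == "hit"],
               oracle_binom_upper(20, 50, 0.02), tolerance = 1e-12)
  expect_true(res$reported[res$term == "hit"])
  expect_false(res$reported[res$term == "null"])
  # fold 1 is never reported
  res2 <- geneset_enrichment_binomial(paste0("g", 1:100), bg,
                                      list(t = paste0("g", seq(2, 1000, 2))))
  expect_false(any(res2$reported))
  expect_error(geneset_enrichment_binomial(fg, character(), sets), "background")
})

test_that("hypergeometric PSG test matches enumeration on tiny instances", {
  set.seed(82)
  for (k in 1:25) {
    N <- sample(6:12, 1)
    genes <- paste0("g", 1:N)
    psg <- sample(genes, sample(2:(N - 1), 1))
    with_rec <- sample(genes, sample(1:N, 1))
    all_links <- data.table::data.table(name = paste0("e", 1:N), gene_id = genes)
    rec_links <- all_links[all_links$gene_id %in% with_rec]
    res <- psg_enrichment(rec_links, all_links, genes, psg)
    k2 <- sum(with_rec %in% psg)
    expect_equal(res$p[2], oracle_hyper_upper(k2, length(psg), N, length(with_rec)),
                 tolerance = 1e-12)
  }
})

test_that("degenerate PSG configurations behave as defined", {
  genes <- paste0("g", 1:10)
  all_links <- data.table::data.table(name = paste0("e", 1:10), gene_id = genes)
  rec_links <- all_links[1:3]
  res <- psg_enrichment(rec_links, all_links, genes, psg_list = genes)
  expect_equal(res$p[2], 1)   # every gene is a PSG
  expect_error(psg_enrichment(rec_links, all_links, genes, character()), "empty")
})

test_that("expression ratio profile normalises per tissue", {
  expr <- rbind(g1 = c(a = 10, b = 10), g2 = c(a = 30, b = 10),
                g3 = c(a = 20, b = 10))
  r <- expression_ratio_profile(c("g1", "g2", "g3"), c("g1", "g2", "g3"), expr)
  expect_equal(unname(r), c(1, 1))
  r2 <- expression_ratio_profile("g2", c("g1", "g3"), expr)
  expect_equal(unname(r2), c(2, 1))
  r3 <- expression_ratio_profile("gX", c("g1", "g2"), expr)
  expect_equal(unname(r3), c(0, 0))
})

test_that("planted PSG association is detected and the null is calibrated", {
  fx <- simulate_psg_fixture(seed = 5, assoc = 3)
  res <- psg_fixture_tests(fx)
  expect_true(all(res$p[1:2] < 0.05))
  fx0 <- simulate_psg_fixture(seed = 6, assoc = 1)
  res0 <- psg_fixture_tests(fx0)
  expect_true(all(res0$p > 0.001))
})
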