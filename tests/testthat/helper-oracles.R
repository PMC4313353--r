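# Brute-force base-level oracles, kept deliberately independent of the
# package's interval machinery: every operation is computed on explicit base
# sets or by direct enumeration.

iv <- function(start, end, species = "s", chrom = "chr1", ...) {
  data.table::data.table(species = species, chrom = chrom,
                         start = start, end = end, ...)
}

bases <- function(start, end) if (end > start) seq(start, end - 1) else integer()

oracle_overlap_bp <- function(a, b) {
  if (a$species != b$species || a$chrom != b$chrom) return(0L)
  length(intersect(bases(a$start, a$end), bases(b$start, b$end)))
}

# maximal runs of the union of covered bases
oracle_merge <- function(x) {
  if (nrow(x) == 0) return(x)
  out <- list()
  for (ch in sort(unique(x$chrom))) {
    b <- sort(unique(unlist(Map(bases, x$start[x$chrom == ch], x$end[x$chrom == ch]))))
    if (!length(b)) next
    run_start <- b[c(TRUE, diff(b) != 1)]
    run_end <- b[c(diff(b) != 1, TRUE)] + 1
    out[[ch]] <- data.table::data.table(species = x$species[1], chrom = ch,
                                        start = run_start, end = run_end)
  }
  data.table::rbindlist(out)
}

# consensus peaks by direct enumeration of the qualifying-overlap definition
oracle_consensus <- function(pk, min_replicates = 2, min_overlap = 0.5) {
  n <- nrow(pk)
  qual <- matrix(FALSE, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b || pk$replicate[a] == pk$replicate[b]) next
    o <- oracle_overlap_bp(pk[a], pk[b])
    if (o / min(pk$end[a] - pk$start[a], pk$end[b] - pk$start[b]) >= min_overlap) {
      qual[a, b] <- TRUE
    }
  }
  good <- vapply(seq_len(n), function(a) {
    length(unique(pk$replicate[qual[a, ]])) >= min_replicates - 1
  }, logical(1))
  # transitive closure over qualifying overlaps among good peaks
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (a in which(good)) for (b in which(good)) {
      if (qual[a, b] && comp[b] != comp[a]) {
        comp[comp == comp[b]] <- comp[a]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  grps <- unique(comp[good])
  res <- data.table::rbindlist(lapply(grps, function(g) {
    m <- which(comp == g & good)
    data.table::data.table(start = min(pk$start[m]), end = max(pk$end[m]),
                           intensity = mean(pk$fold_enrichment[m]),
                           n_replicates = length(unique(pk$replicate[m])))
  }))
  if (nrow(res)) data.table::setorder(res, start)
  res
}

# GREAT-style domain for one gene by direct per-gene scan: the extension on
# each side reaches the basal edge of the nearest gene on that side (by TSS),
# truncating to zero extension when that basal already overlaps ours
oracle_domain <- function(genes, k, chrom_len, basal_up = 5000, basal_down = 1000,
                          max_ext = 1e6) {
  g <- genes[k]
  basal <- function(tss, strand) {
    if (strand == "+") c(tss - basal_up, tss + basal_down)
    else c(tss - basal_down, tss + basal_up)
  }
  b <- basal(g$tss, g$strand)
  bs <- max(0, b[1]); be <- min(chrom_len, b[2])
  left <- bs - max_ext
  right <- be + max_ext
  for (j in seq_len(nrow(genes))) {
    if (j == k || genes$chrom[j] != g$chrom) next
    ob <- basal(genes$tss[j], genes$strand[j])
    obs <- max(0, ob[1]); obe <- min(chrom_len, ob[2])
    if (genes$tss[j] < g$tss) left <- max(left, min(obe, bs))
    if (genes$tss[j] > g$tss) right <- min(right, max(obs, be))
  }
  c(max(0, min(bs, left)), min(chrom_len, max(be, right)))
}

# exact upper-tail binomial by log-space summation
oracle_binom_upper <- function(k, n, p) {
  if (k <= 0) return(1)
  if (k > n) return(0)
  sum(exp(lchoose(n, k:n) + (k:n) * log(p) + (n - (k:n)) * log1p(-p)))
}

# exact hypergeometric upper tail by enumeration
oracle_hyper_upper <- function(k, K, N, n) {
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

tiny_tree <- function() {
  ape::read.tree(text = "((A:50,B:50):40,C:90);")
}

small_world_config <- function(seed = 7, ...) {
  tr <- ape::keep.tip(mammal_tree(),
                      c("human", "macaque", "marmoset", "mouse", "cow", "opossum"))
  defaults <- list(
    seed = seed, tree = tr, n_root_blocks = 1200L,
    classes = data.frame(class = c("promoter_dual", "promoter_k4", "enhancer"),
                         n_root = c(150L, 50L, 300L),
                         half_life = c(900, 900, 300),
                         birth_rate = c(0.15, 0.05, 0.8),
                         frac_young = c(0.25, 0.25, 0.35)),
    young_block_rate = 0.5, n_genes = 80L, n_psg = 10L)
  extra <- list(...)
  args <- defaults
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

noise_free <- function(cfg) {
  cfg$sensitivity <- 1; cfg$fp_rate <- 0; cfg$jitter_frac <- 0
  cfg$mark_switch <- 0; cfg$sens_slope <- 0
  cfg
}
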