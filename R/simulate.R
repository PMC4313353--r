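#' Configuration for the synthetic genome-evolution generator
#'
#' The generator emulates the data-generating process behind a multi-species
#' histone-mark ChIP-seq study: a dated phylogeny, per-species genomes made of
#' orthologous DNA blocks that are gained and lost along the tree (DNA
#' turnover), regulatory elements born and lost on branches with class-specific
#' exponential half-lives (activity turnover, independent of DNA turnover),
#' replicate peak calls with intensity-dependent detection noise, repeat
#' annotations with a configurable young-DNA bias, and a gene/expression layer
#' with a planted association between recently evolved enhancers and
#' positively selected genes (PSGs).
#'
#' Defaults describe the study conditions: 20 taxa spanning 180 Ma, promoter
#' half-life 900 Ma, enhancer half-life 300 Ma, 3 biological replicates per
#' species (1 for `sei_whale`), per-replicate detection sensitivity 0.92.
#'
#' @param seed integer seed; the whole world is deterministic given the seed.
#' @param tree dated `ape::phylo` (branch lengths in Ma); default the bundled
#'   20-taxon mammal tree.
#' @param anchor reference species for human-centric analyses.
#' @param classes data.frame with columns `class`, `n_root`, `half_life` (Ma),
#'   `birth_rate` (births/Ma genome-wide), `frac_young` (fraction of births
#'   placed in lineage-restricted young DNA).
#' @param n_root_blocks number of ancestral (root) DNA blocks.
#' @param block_length,spacer bp; each block is separated by unaligned spacer.
#' @param young_block_rate background young-DNA blocks per Ma per branch.
#' @param align_half_life per-lineage half-life (Ma) of DNA alignability.
#' @param n_replicates replicates per species/mark.
#' @param single_replicate_species species profiled with one replicate only.
#' @param sensitivity mean per-replicate detection probability of a true
#'   element occurrence.
#' @param sens_slope logistic slope of detection on centred log intensity
#'   (0 = intensity-independent detection).
#' @param fp_rate false-positive peaks per replicate, as a fraction of the
#'   true peak count.
#' @param intensity_meanlog,intensity_sdlog log-normal element intensity.
#' @param rep_noise_sdlog replicate-level multiplicative intensity noise.
#' @param jitter_frac peak-boundary jitter sd as a fraction of element length.
#' @param mark_switch probability that a dual-marked element displays only one
#'   of its two marks in a given species.
#' @param element_length_range bp range of element lengths.
#' @param repeat_families data.frame `family`, `rclass`, `n`, `len`,
#'   `young_bias` for the reference-species repeat annotation.
#' @param n_genes,tissues,n_psg,psg_assoc gene layer: number of genes, tissue
#'   names (first is the target tissue), PSG list size, and the fold-bias of
#'   recent enhancer births into PSG regulatory domains.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       tree = NULL,
                       anchor = "human",
                       classes = data.frame(
                         class = c("promoter_dual", "promoter_k4", "enhancer"),
                         n_root = c(1200L, 400L, 2400L),
                         half_life = c(900, 900, 300),
                         birth_rate = c(0.9, 0.3, 5.5),
                         frac_young = c(0.25, 0.25, 0.35)),
                       n_root_blocks = 14000L,
                       block_length = 3000L,
                       spacer = 1000L,
                       young_block_rate = 2,
                       align_half_life = 1500,
                       n_replicates = 3L,
                       single_replicate_species = "sei_whale",
                       sensitivity = 0.92,
                       sens_slope = 1,
                       fp_rate = 0.05,
                       intensity_meanlog = log(8),
                       intensity_sdlog = 0.5,
                       rep_noise_sdlog = 0.25,
                       jitter_frac = 0.08,
                       mark_switch = 0.05,
                       element_length_range = c(800L, 2200L),
                       repeat_families = default_repeat_families(),
                       n_genes = 400L,
                       tissues = c("liver", "brain", "heart", "kidney", "muscle", "testis"),
                       n_psg = 40L,
                       psg_assoc = 3) {
  cfg <- as.list(environment())
  stopifnot(all(cfg$classes$half_life > 0),
            all(cfg$classes$birth_rate >= 0),
            cfg$n_replicates >= 1,
            cfg$sensitivity > 0, cfg$sensitivity <= 1,
            cfg$fp_rate >= 0)
  class(cfg) <- "sim_config"
  cfg
}

#' @rdname sim_config
#' @export
default_repeat_families <- function() {
  data.frame(
    family = c("L1", "L2", "AluY", "AluS", "MIR", "ERV1", "ERVL", "MaLR",
               "hAT-Charlie", "TcMar-Tigger", "SVA", "CR1"),
    rclass = c("LINE", "LINE", "SINE", "SINE", "SINE", "LTR", "LTR", "LTR",
               "DNA", "DNA", "Retroposon", "LINE"),
    n = c(900, 500, 700, 800, 600, 350, 350, 400, 300, 250, 120, 200),
    len = c(900, 500, 300, 300, 200, 600, 500, 400, 250, 250, 800, 400),
    young_bias = c(0.5, 0.05, 0.7, 0.3, 0.02, 0.6, 0.2, 0.15, 0.05, 0.05, 0.8, 0.05),
    stringsAsFactors = FALSE)
}

# marks displayed by each element class
class_marks <- function(cls) {
  switch(cls,
         promoter_dual = c("H3K4me3", "H3K27ac"),
         promoter_k4 = "H3K4me3",
         enhancer = "H3K27ac",
         stop("unknown class: ", cls))
}

# presence propagation along the tree: items born at `birth_node` (the child
# node of their birth branch; root-born items have birth_node == root) are
# lost on each branch with per-Ma rate `rate` (= ln2 / half-life); loss is
# inherited by the whole subtree below. Returns items x nodes logical matrix.
propagate_presence <- function(birth_node, birth_age, tree, rate) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  ed <- edge_table(tree)
  n <- length(birth_node)
  M <- matrix(FALSE, n, n_node)
  M[birth_node == root, root] <- TRUE
  for (e in seq_len(nrow(ed))) {
    p <- ed$parent[e]; ch <- ed$child[e]
    alive_p <- which(M[, p])
    if (length(alive_p)) {
      M[alive_p, ch] <- stats::runif(length(alive_p)) < exp(-rate * ed$length[e])
    }
    born_here <- which(birth_node == ch)
    if (length(born_here)) {
      dt_ma <- pmax(0, birth_age[born_here] - ed$age_child[e])
      M[born_here, ch] <- stats::runif(length(born_here)) < exp(-rate * dt_ma)
    }
  }
  M
}

# solve the detection-logit intercept so that mean detection == sensitivity
detection_probs <- function(log_int_centred, sensitivity, slope) {
  if (sensitivity >= 1) return(rep(1, length(log_int_centred)))
  if (slope == 0) return(rep(sensitivity, length(log_int_centred)))
  f <- function(a) mean(stats::plogis(a + slope * log_int_centred)) - sensitivity
  a <- stats::uniroot(f, c(-20, 20))$root
  stats::plogis(a + slope * log_int_centred)
}

#' Simulate a complete synthetic study
#'
#' Runs the generative model described in [sim_config()] and returns a
#' `synth_world`: the tree, DNA blocks with per-species presence, the true
#' element registry with per-species activity, replicate peak calls, repeats,
#' genes, expression, the PSG list, and coverage vectors for the
#' false-negative check. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return object of class `synth_world`.
#' @export
simulate_world <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tree <- config$tree
  if (is.null(tree)) tree <- mammal_tree()
  if (length(tree$tip.label) < 2) stop("degenerate tree: need >= 2 taxa")
  set.seed(config$seed)

  species <- tree$tip.label
  n_tip <- length(species)
  root <- n_tip + 1L
  ages <- node_ages(tree)
  ed <- edge_table(tree)
  log2c <- log(2)
  ctab <- data.table::as.data.table(config$classes)
  anchor_i <- match(config$anchor, species)
  if (is.na(anchor_i)) stop("anchor species not in tree")
  align_rate <- log2c / config$align_half_life

  ## --- DNA blocks: ancestral + background young --------------------------
  blocks <- data.table::data.table(
    block_id = seq_len(config$n_root_blocks),
    birth_node = root,
    birth_age = ages[root],
    slot = stats::runif(config$n_root_blocks))
  for (e in seq_len(nrow(ed))) {
    nb <- stats::rpois(1, config$young_block_rate * ed$length[e])
    if (nb > 0) {
      blocks <- rbind(blocks, data.table::data.table(
        block_id = max(blocks$block_id) + seq_len(nb),
        birth_node = ed$child[e],
        birth_age = stats::runif(nb, ed$age_child[e], ed$age_parent[e]),
        slot = stats::runif(nb)))
    }
  }
  # authoritative presence for these blocks (element-born blocks added later)
  Mb0 <- propagate_presence(blocks$birth_node, blocks$birth_age, tree, align_rate)

  ## --- element births -----------------------------------------------------
  el <- list()
  for (ci in seq_len(nrow(ctab))) {
    cls <- ctab$class[ci]
    births <- list()
    if (ctab$n_root[ci] > 0) {
      births[[1]] <- data.table::data.table(class = cls, birth_node = root,
                                            birth_age = ages[root],
                                            young = FALSE)[rep(1, ctab$n_root[ci])]
    }
    if (ctab$birth_rate[ci] > 0) {
      for (e in seq_len(nrow(ed))) {
        nb <- stats::rpois(1, ctab$birth_rate[ci] * ed$length[e])
        if (nb > 0) {
          births[[length(births) + 1]] <- data.table::data.table(
            class = cls, birth_node = ed$child[e],
            birth_age = stats::runif(nb, ed$age_child[e], ed$age_parent[e]),
            young = stats::runif(nb) < ctab$frac_young[ci])
        }
      }
    }
    el[[length(el) + 1]] <- data.table::rbindlist(births)
  }
  elements <- data.table::rbindlist(el)
  elements[, id := sprintf("e%05d", .I)]
  elements[, block_id := NA_integer_]

  ## --- root elements take ancestral blocks first --------------------------
  pool <- sample(seq_len(config$n_root_blocks))
  draw_pool <- function(n, w = NULL) {
    if (n > length(pool)) stop("ancestral block pool exhausted; raise n_root_blocks")
    if (is.null(w)) picked <- pool[seq_len(n)]
    else picked <- sample(pool, n, prob = w[as.character(pool)])
    pool <<- setdiff(pool, picked)
    picked
  }
  root_idx <- which(elements$birth_node == root)
  elements$block_id[root_idx] <- draw_pool(length(root_idx))

  ## --- genes near root promoter blocks; PSG list --------------------------
  # genes sit preferentially in the same DNA block as a root promoter, so
  # promoters cluster at TSSs; only blocks present in the anchor host genes
  anchor_blocks0 <- blocks$block_id[Mb0[, anchor_i]]
  prom_blocks <- intersect(
    elements$block_id[root_idx][elements$class[root_idx] == "promoter_dual"],
    anchor_blocks0)
  n_at_prom <- min(round(0.6 * config$n_genes), length(prom_blocks))
  host <- c(sample(prom_blocks, n_at_prom),
            sample(setdiff(anchor_blocks0, prom_blocks), config$n_genes - n_at_prom))
  genes <- data.table::data.table(
    gene_id = sprintf("g%04d", seq_len(config$n_genes)),
    host_block = host,
    host_offset = round(stats::runif(config$n_genes, 0.1, 0.9) * config$block_length),
    strand = sample(c("+", "-"), config$n_genes, TRUE))
  psg <- sort(sample(genes$gene_id, config$n_psg))

  # provisional anchor layout (root + background blocks) to mark blocks that
  # fall inside PSG regulatory domains; used only to bias placement below
  prov <- layout_blocks(blocks[Mb0[, anchor_i]], config)
  gtab0 <- data.table::data.table(
    gene_id = genes$gene_id, chrom = "chr1",
    tss = prov$start[match(genes$host_block, prov$block_id)] + genes$host_offset,
    strand = genes$strand)
  dom0 <- suppressWarnings(   # genes near chromosome ends clip routinely
    build_regulatory_domains(gtab0, chrom_lengths = c(chr1 = prov_len(prov, config))))
  psg_dom <- dom0[dom0$gene_id %in% psg, ]
  mid <- prov$start + config$block_length / 2
  prox <- rep(FALSE, nrow(prov))
  for (k in seq_len(nrow(psg_dom))) {
    prox <- prox | (mid >= psg_dom$dom_start[k] & mid < psg_dom$dom_end[k])
  }
  psg_proximal <- prov$block_id[prox]

  ## --- branch-born elements: ancestral (exapted) or young DNA ------------
  is_recent_enh <- elements$class == "enhancer" & elements$birth_node == anchor_i
  w_tab <- stats::setNames(ifelse(seq_len(config$n_root_blocks) %in% psg_proximal,
                                  config$psg_assoc, 1),
                           as.character(seq_len(config$n_root_blocks)))
  rec_anc <- which(!elements$young & is_recent_enh & is.na(elements$block_id))
  if (length(rec_anc)) elements$block_id[rec_anc] <- draw_pool(length(rec_anc), w_tab)
  oth_anc <- which(!elements$young & is.na(elements$block_id))
  if (length(oth_anc)) elements$block_id[oth_anc] <- draw_pool(length(oth_anc))

  yng <- which(elements$young)
  Mb_new <- NULL
  if (length(yng)) {
    slot_y <- stats::runif(length(yng))
    rec_y <- is_recent_enh[yng]
    if (any(rec_y)) {
      wsel <- ifelse(prov$block_id %in% psg_proximal, config$psg_assoc, 1)
      near <- sample(seq_len(nrow(prov)), sum(rec_y), TRUE, prob = wsel)
      slot_y[rec_y] <- blocks$slot[match(prov$block_id[near], blocks$block_id)] +
        stats::runif(sum(rec_y), 0, 1e-4)
    }
    newb <- data.table::data.table(
      block_id = max(blocks$block_id) + seq_along(yng),
      birth_node = elements$birth_node[yng],
      birth_age = elements$birth_age[yng],
      slot = slot_y)
    elements$block_id[yng] <- newb$block_id
    Mb_new <- propagate_presence(newb$birth_node, newb$birth_age, tree, align_rate)
    blocks <- rbind(blocks, newb)
  }

  Mb <- if (is.null(Mb_new)) Mb0 else rbind(Mb0, Mb_new)
  block_presence <- Mb[, seq_len(n_tip), drop = FALSE]
  colnames(block_presence) <- species
  rownames(block_presence) <- as.character(blocks$block_id)

  ## --- element activity presence ------------------------------------------
  active <- matrix(FALSE, nrow(elements), n_tip,
                   dimnames = list(elements$id, species))
  for (ci in seq_len(nrow(ctab))) {
    idx <- which(elements$class == ctab$class[ci])
    if (!length(idx)) next
    rate <- if (is.finite(ctab$half_life[ci])) log2c / ctab$half_life[ci] else 0
    Ma <- propagate_presence(elements$birth_node[idx], elements$birth_age[idx],
                             tree, rate)
    active[idx, ] <- Ma[, seq_len(n_tip), drop = FALSE]
  }
  # activity requires the underlying DNA to still exist
  bp_el <- block_presence[match(elements$block_id, blocks$block_id), , drop = FALSE]
  active <- active & bp_el

  ## --- element geometry, intensity, sequence features --------------------
  n_el <- nrow(elements)
  elements[, length := round(stats::runif(n_el, config$element_length_range[1],
                                          config$element_length_range[2]))]
  elements[, offset := round(stats::runif(n_el) * (config$block_length - length))]
  elements[, intensity := stats::rlnorm(n_el, config$intensity_meanlog,
                                        config$intensity_sdlog)]
  elements[, gc := pmin(0.8, pmax(0.2, stats::rnorm(
    n_el, ifelse(class == "enhancer", 0.45, 0.58), 0.05)))]
  elements[, constraint := pmin(1, stats::rbeta(n_el, 1.2, 8) +
                                  ifelse(birth_node == root, 0.08, 0))]
  elements[, tfbs := stats::rpois(n_el, 2 + 12 * constraint)]
  elements[, p_det := detection_probs(log(intensity) - config$intensity_meanlog,
                                      config$sensitivity, config$sens_slope)]

  ## --- displayed mark state per species (0 none, 1 dual, 2 k4, 3 k27) ----
  state <- matrix(0L, n_el, n_tip, dimnames = list(elements$id, species))
  base_state <- c(promoter_dual = 1L, promoter_k4 = 2L,
                  enhancer = 3L)[elements$class]
  state[active] <- rep(base_state, n_tip)[as.vector(active)]
  if (config$mark_switch > 0) {
    dual_cells <- which(state == 1L)
    sw <- dual_cells[stats::runif(length(dual_cells)) < config$mark_switch]
    if (length(sw)) state[sw] <- sample(c(2L, 3L), length(sw), TRUE)
  }

  ## --- per-species genome layouts -----------------------------------------
  layouts <- lapply(seq_len(n_tip), function(s) {
    layout_blocks(blocks[block_presence[, s]], config)
  })
  names(layouts) <- species

  ## --- replicate peak calls ----------------------------------------------
  peaks <- emit_peaks(elements, state, layouts, species, config)

  ## --- repeats (anchor) ----------------------------------------------------
  repeats <- emit_repeats(blocks, block_presence[, anchor_i],
                          layouts[[anchor_i]], config)

  ## --- gene coordinates on the final anchor layout ------------------------
  lay_a <- layouts[[anchor_i]]
  hb <- match(genes$host_block, lay_a$block_id)
  genes_out <- data.table::data.table(
    gene_id = genes$gene_id, chrom = "chr1",
    tss = lay_a$start[hb] + genes$host_offset,
    strand = genes$strand)

  ## --- expression, constrained elements, coverage -------------------------
  expr <- simulate_expression(genes_out$gene_id, config$tissues)
  constrained <- emit_constrained(elements, lay_a, active[, anchor_i], config)
  coverage <- emit_coverage(elements, active, bp_el, anchor_i, config)

  world <- list(config = config, tree = tree, species = species,
                anchor = config$anchor,
                blocks = blocks, block_presence = block_presence,
                elements = elements, active = active, state = state,
                layouts = layouts, peaks = peaks, repeats = repeats,
                genes = genes_out, expr = expr, psg = psg,
                constrained = constrained, coverage = coverage)
  class(world) <- "synth_world"
  world
}

# lay out a set of blocks along a single chromosome, ordered by slot
layout_blocks <- function(b, config) {
  b <- b[order(b$slot)]
  data.table::data.table(
    block_id = b$block_id,
    start = (seq_len(nrow(b)) - 1) * (config$block_length + config$spacer))
}

prov_len <- function(lay, config) {
  nrow(lay) * (config$block_length + config$spacer)
}

#' Genome length of one species in a synthetic world
#' @param world a `synth_world`.
#' @param species species id.
#' @return named numeric (chromosome lengths, bp).
#' @export
world_chrom_lengths <- function(world, species) {
  c(chr1 = prov_len(world$layouts[[species]], world$config))
}

#' @export
print.synth_world <- function(x, ...) {
  cat("synth_world:", length(x$species), "species,", nrow(x$elements),
      "true elements,", nrow(x$blocks), "DNA blocks,",
      nrow(x$peaks), "replicate peaks\n")
  invisible(x)
}

emit_peaks <- function(elements, state, layouts, species, config) {
  out <- list()
  for (s in seq_along(species)) {
    sp <- species[s]
    lay <- layouts[[s]]
    n_rep <- if (sp %in% config$single_replicate_species) 1L else config$n_replicates
    st <- state[, s]
    idx <- which(st > 0L)
    if (!length(idx)) next
    bpos <- lay$start[match(elements$block_id[idx], lay$block_id)]
    estart <- bpos + elements$offset[idx]
    eend <- estart + elements$length[idx]
    nmk <- ifelse(st[idx] == 1L, 2L, 1L)
    mark <- character(sum(nmk))
    pos <- cumsum(nmk)
    mark[pos[st[idx] == 2L]] <- "H3K4me3"
    mark[pos[st[idx] == 3L]] <- "H3K27ac"
    dual <- which(st[idx] == 1L)
    mark[pos[dual]] <- "H3K27ac"
    mark[pos[dual] - 1L] <- "H3K4me3"
    base <- data.table::data.table(
      el = rep(idx, nmk),
      start0 = rep(estart, nmk), end0 = rep(eend, nmk),
      mark = mark)
    for (r in seq_len(n_rep)) {
      det <- stats::runif(nrow(base)) < elements$p_det[base$el]
      pk <- base[det]
      if (nrow(pk)) {
        len <- pk$end0 - pk$start0
        js <- round(stats::rnorm(nrow(pk), 0, config$jitter_frac * len))
        je <- round(stats::rnorm(nrow(pk), 0, config$jitter_frac * len))
        s2 <- pmax(0, pk$start0 + js); e2 <- pk$end0 + je
        bad <- s2 >= e2
        s2[bad] <- pk$start0[bad]; e2[bad] <- pk$end0[bad]
        fold <- elements$intensity[pk$el] *
          exp(stats::rnorm(nrow(pk), 0, config$rep_noise_sdlog))
        out[[length(out) + 1]] <- data.table::data.table(
          species = sp, chrom = "chr1", start = s2, end = e2,
          name = elements$id[pk$el], score = round(10 * fold),
          strand = ".", fold_enrichment = fold, mark = pk$mark, replicate = r)
      }
      for (m in c("H3K4me3", "H3K27ac")) {
        n_fp <- stats::rpois(1, config$fp_rate * sum(base$mark == m))
        if (n_fp > 0) {
          bi <- sample(nrow(lay), n_fp, TRUE)
          fl <- round(stats::runif(n_fp, 600, 1500))
          fs <- lay$start[bi] + round(stats::runif(n_fp) * (config$block_length - fl))
          fold <- stats::rlnorm(n_fp, log(4), 0.4)
          out[[length(out) + 1]] <- data.table::data.table(
            species = sp, chrom = "chr1", start = pmax(0, fs),
            end = pmax(0, fs) + fl,
            name = sprintf("fp_%s_%s_r%d_%d", sp, m, r, seq_len(n_fp)),
            score = round(10 * fold), strand = ".",
            fold_enrichment = fold, mark = m, replicate = r)
        }
      }
    }
  }
  pk <- data.table::rbindlist(out)
  if (nrow(pk) == 0) {
    pk <- data.table::data.table(species = character(), chrom = character(),
                                 start = numeric(), end = numeric(),
                                 name = character(), score = numeric(),
                                 strand = character(),
                                 fold_enrichment = numeric(),
                                 mark = character(), replicate = integer())
  }
  data.table::setorder(pk, species, mark, replicate, chrom, start)
  pk[]
}

emit_repeats <- function(blocks, present_anchor, lay, config) {
  fam <- config$repeat_families
  pres <- blocks[present_anchor]
  young <- which(pres$birth_age < 40)
  out <- list()
  for (i in seq_len(nrow(fam))) {
    n <- fam$n[i]
    pick_young <- stats::runif(n) < fam$young_bias[i] & length(young) > 0
    bi <- integer(n)
    if (any(pick_young)) bi[pick_young] <- sample(young, sum(pick_young), TRUE)
    bi[!pick_young] <- sample(nrow(pres), sum(!pick_young), TRUE)
    len <- pmin(config$block_length,
                pmax(50, round(stats::rnorm(n, fam$len[i], fam$len[i] / 5))))
    st <- lay$start[match(pres$block_id[bi], lay$block_id)] +
      round(stats::runif(n) * (config$block_length - len))
    out[[i]] <- data.table::data.table(
      species = config$anchor, chrom = "chr1", start = st, end = st + len,
      name = sprintf("%s_%d", fam$family[i], seq_len(n)), score = 0L,
      strand = ".", rclass = fam$rclass[i], family = fam$family[i])
  }
  rp <- data.table::rbindlist(out)
  data.table::setorder(rp, chrom, start)
  rp[]
}

simulate_expression <- function(gene_ids, tissues) {
  n <- length(gene_ids)
  k <- length(tissues)
  type <- sample(c("target", "other", "ubiq", "off"), n, TRUE,
                 prob = c(0.15, 0.25, 0.55, 0.05))
  m <- matrix(0, n, k, dimnames = list(gene_ids, tissues))
  for (i in seq_len(n)) {
    m[i, ] <- switch(type[i],
      target = { v <- stats::rlnorm(k, log(3), 0.8)
                 v[1] <- stats::rlnorm(1, log(60), 0.6); v },
      other = { v <- stats::rlnorm(k, log(3), 0.8)
                v[sample(2:k, 1)] <- stats::rlnorm(1, log(60), 0.6); v },
      ubiq = stats::rlnorm(k, log(20), 0.5),
      off = rep(0, k))
  }
  m
}

emit_constrained <- function(elements, lay_a, active_anchor, config) {
  # one constrained sub-interval per anchor-active element covering its
  # planted constraint fraction, plus diffuse background intervals
  idx <- which(active_anchor)
  out <- list()
  if (length(idx)) {
    bpos <- lay_a$start[match(elements$block_id[idx], lay_a$block_id)]
    estart <- bpos + elements$offset[idx]
    clen <- round(elements$constraint[idx] * elements$length[idx])
    keep <- which(clen > 0)
    if (length(keep)) {
      cs <- estart[keep] + round(stats::runif(length(keep)) *
                                   (elements$length[idx][keep] - clen[keep]))
      out[[1]] <- data.table::data.table(species = config$anchor, chrom = "chr1",
                                         start = cs, end = cs + clen[keep])
    }
  }
  nbg <- 2000L
  bi <- sample(nrow(lay_a), nbg, TRUE)
  bl <- round(stats::runif(nbg, 20, 200))
  bs <- lay_a$start[bi] + round(stats::runif(nbg) * (config$block_length - bl))
  out[[length(out) + 1]] <- data.table::data.table(
    species = config$anchor, chrom = "chr1", start = bs, end = bs + bl)
  cons <- data.table::rbindlist(out)
  merge_interval_set(cons[start < end])
}

emit_coverage <- function(elements, active, bp_el, anchor_i, config) {
  # read-coverage emulation at orthologous locations of anchor elements
  # called absent elsewhere: truly-absent sites carry background coverage,
  # detection-missed sites carry signal-like coverage
  anch <- active[, anchor_i]
  other <- setdiff(seq_len(ncol(active)), anchor_i)
  truly_absent <- sum(bp_el[anch, other] & !active[anch, other])
  present <- sum(active[anch, other])
  nr <- config$n_replicates
  p_miss_cons <- mean((1 - elements$p_det[anch])^nr +
                        nr * elements$p_det[anch] *
                        (1 - elements$p_det[anch])^(nr - 1))
  missed <- if (present > 0 && is.finite(p_miss_cons)) {
    stats::rbinom(1, present, p_miss_cons)
  } else 0L
  list(control = stats::rnorm(2000, 10, 2),
       absent = c(stats::rnorm(truly_absent, 10, 2),
                  stats::rnorm(missed, 18, 3)))
}
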