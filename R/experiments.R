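#' Half-life recovery experiment on the high-quality panel
#'
#' Simulates the ten-species high-quality panel with planted promoter and
#' enhancer half-lives and a fixed root cohort per class (ongoing births and
#' mark switching disabled so the measured pairwise decay reflects the
#' planted loss process alone), computes both pairwise conservation-ratio
#' matrices, and fits the exponential decay per class. Repeated over seeds
#' to assess CI coverage of the planted values.
#'
#' @param n_seeds number of independent simulated studies.
#' @param seed0 base seed; run `k` uses `seed0 + k`.
#' @param promoter_hl,enhancer_hl planted half-lives (Ma).
#' @param n_per_class root elements per class.
#' @param panel_species species kept from the bundled tree.
#' @return data.table with one row per run and class: fitted `half_life`,
#'   `ci_lo`, `ci_hi`, `covered` (planted value inside the fitted CI),
#'   `r2`.
#' @export
experiment_halflife_recovery <- function(n_seeds = 20L, seed0 = 100L,
                                         promoter_hl = 900, enhancer_hl = 300,
                                         n_per_class = 5000L,
                                         panel_species = c("human", "macaque",
                                                           "marmoset", "mouse", "rat",
                                                           "rabbit", "cow", "pig",
                                                           "dog", "cat")) {
  tr <- ape::keep.tip(mammal_tree(), panel_species)
  planted <- c(promoter = promoter_hl, enhancer = enhancer_hl)
  out <- list()
  for (k in seq_len(n_seeds)) {
    # single-mark promoter cohort: a dual promoter whose H3K4me3 consensus is
    # missed in one species would be misclassified as an enhancer there and
    # contaminate the enhancer cohort with slow-decaying elements; K4-only
    # promoters keep the two cohorts cleanly separated
    cfg <- sim_config(
      seed = seed0 + k, tree = tr,
      classes = data.frame(class = c("promoter_k4", "enhancer"),
                           n_root = c(n_per_class, n_per_class),
                           half_life = c(promoter_hl, enhancer_hl),
                           birth_rate = 0, frac_young = 0),
      mark_switch = 0, n_genes = 100L, n_psg = 10L)
    w <- simulate_world(cfg)
    cons <- consensus_all(w)
    mats <- conservation_ratio_matrices(w, cons)
    for (g in names(mats)) {
      fit <- fit_exponential_decay(decay_points(mats[[g]], tr))
      out[[length(out) + 1]] <- data.table::data.table(
        run = k, class = g, planted = planted[[g]],
        half_life = fit$half_life,
        ci_lo = fit$ci95_half_life[1], ci_hi = fit$ci95_half_life[2],
        covered = planted[[g]] >= fit$ci95_half_life[1] &
          planted[[g]] <= fit$ci95_half_life[2],
        r2 = fit$r_squared)
    }
  }
  data.table::rbindlist(out)
}

#' Anchor-centric conservation profile of a world
#'
#' Convenience wrapper computing the conservation profile of one species'
#' classified elements against all other species of the world.
#'
#' @param world a `synth_world`.
#' @param cons output of [consensus_all()].
#' @param ref reference (anchor) species.
#' @param min_overlap required overlap fraction.
#' @return see [conservation_profile()].
#' @export
world_profile <- function(world, cons, ref, min_overlap = 0.5) {
  others <- setdiff(world$species, ref)
  maps <- lapply(others, function(s) orthology_map(world, ref, s))
  names(maps) <- others
  tg <- lapply(others, function(s) list(k4 = cons[[s]]$k4, k27 = cons[[s]]$k27))
  names(tg) <- others
  conservation_profile(cons[[ref]]$elements, maps, tg, min_overlap)
}

#' Match consensus elements back to true world elements
#'
#' Assigns each consensus element the id of the true element it overlaps
#' most (NA for consensus regions without a true active element, e.g. built
#' from false-positive peaks).
#'
#' @param world a `synth_world`.
#' @param elements consensus elements in `species` coordinates.
#' @param species species id.
#' @return character vector of true element ids (NA where unmatched).
#' @export
match_truth <- function(world, elements, species) {
  lay <- world$layouts[[species]]
  act <- which(world$active[, species])
  ts <- lay$start[match(world$elements$block_id[act], lay$block_id)] +
    world$elements$offset[act]
  tdt <- data.table::data.table(species = species, chrom = "chr1", start = ts,
                                end = ts + world$elements$length[act],
                                id = world$elements$id[act])
  hits <- as.data.frame(interval_overlaps(elements, tdt))
  hits <- hits[order(-hits$ov), ]
  hits <- hits[!duplicated(hits$i), ]
  out <- rep(NA_character_, nrow(elements))
  out[hits$i] <- tdt$id[hits$j]
  out
}

#' Phylogeny recovery from conservation distances
#'
#' Builds the neighbor-joining tree from enhancer non-conservation distances
#' (1 - pairwise ratio) on the default 20-taxon world and reports its
#' Robinson-Foulds distance to the generating topology; also runs the
#' no-loss promoter limit (near-infinite half-life, no births), whose
#' distance matrix should be near-star.
#'
#' @param seed integer seed.
#' @return list: `rf` (Robinson-Foulds distance, enhancers),
#'   `max_promoter_distance` (no-loss limit), `nj` (the enhancer NJ tree).
#' @export
experiment_phylogeny_recovery <- function(seed = 1L) {
  w <- simulate_world(sim_config(seed = seed))
  cons <- consensus_all(w)
  m_e <- conservation_ratio_matrices(w, cons, groups = "enhancer")$enhancer
  nj <- nj_tree(1 - m_e)
  rf <- ape::dist.topo(ape::unroot(nj), ape::unroot(w$tree), method = "PH85")
  cfg2 <- sim_config(
    seed = seed + 1L,
    classes = data.frame(class = c("promoter_dual", "promoter_k4"),
                         n_root = c(1200L, 400L), half_life = 1e9,
                         birth_rate = 0, frac_young = 0))
  w2 <- simulate_world(cfg2)
  cons2 <- consensus_all(w2)
  m_p <- conservation_ratio_matrices(w2, cons2, groups = "promoter")$promoter
  list(rf = as.numeric(rf), max_promoter_distance = max(1 - m_p[upper.tri(m_p)]),
       nj = nj)
}

#' End-to-end truth recovery of recent and lineage-specific calls
#'
#' Runs the full default study once, calls recently evolved and
#' lineage-specific elements, and scores them against the generator's truth
#' registry: precision/recall for recent calls (truth = elements born on the
#' anchor's terminal branch) and pooled over the four study clades for
#' lineage-specific calls (truth = born on the clade stem and active in all
#' designated species); also the young-DNA fraction among recent enhancers
#' against the configured birth placement.
#'
#' @param seed integer seed.
#' @return list of metrics.
#' @export
experiment_truth_recovery <- function(seed = 7L) {
  w <- simulate_world(sim_config(seed = seed))
  cons <- consensus_all(w)
  pan <- default_panel()
  pr <- world_profile(w, cons, pan$anchor)
  rec <- find_recently_evolved(cons[[pan$anchor]]$elements, pr$calls)
  tid <- match_truth(w, rec, pan$anchor)
  anchor_node <- match(pan$anchor, w$species)
  tru_terminal <- w$elements$id[w$elements$birth_node == anchor_node]
  tru_set <- intersect(tru_terminal, w$elements$id[w$active[, pan$anchor]])
  recent_precision <- mean(tid %in% tru_terminal)
  recent_recall <- mean(tru_set %in% tid)
  ages <- sequence_ages(pr$calls, w$tree, pan$anchor)
  rec_rows <- match(rec$name, cons[[pan$anchor]]$elements$name)
  recE <- rec$assigned_class == "enhancer"
  young_frac <- mean(ages$category[rec_rows][recE] == "young")
  f_young <- w$config$classes$frac_young[w$config$classes$class == "enhancer"]
  ls_called <- 0; ls_tp <- 0; ls_truth <- 0; ls_found <- 0
  for (cl in pan$clades) {
    prr <- if (cl$reference == pan$anchor) pr else world_profile(w, cons, cl$reference)
    ls <- find_lineage_specific(cons[[cl$reference]]$elements, prr$calls,
                                prr$states, cl)
    crown <- ape::getMRCA(w$tree, cl$members)
    tru_ls <- w$elements$id[w$elements$birth_node == crown &
      rowSums(w$active[, cl$required, drop = FALSE]) == length(cl$required)]
    tid_ls <- match_truth(w, ls, cl$reference)
    ls_called <- ls_called + nrow(ls)
    ls_tp <- ls_tp + sum(tid_ls %in% tru_ls)
    ls_truth <- ls_truth + length(tru_ls)
    ls_found <- ls_found + sum(tru_ls %in% tid_ls)
  }
  list(recent_precision = recent_precision, recent_recall = recent_recall,
       n_recent = nrow(rec), n_recent_enh = sum(recE),
       young_frac = young_frac, young_frac_expected = f_young,
       lineage_precision = ls_tp / ls_called, lineage_recall = ls_found / ls_truth,
       n_lineage = ls_called)
}

#' Permutation-test calibration under a null labelling
#'
#' For each seed, draws random per-species/per-mark conserved subsets of a
#' fixed universe, computes the observed panel-wide conserved count from one
#' literal labelling, and the permutation p-value; under the null the
#' p-values are uniform.
#'
#' @param n_seeds number of null studies.
#' @param seed0 base seed.
#' @param n_universe anchor elements in the universe.
#' @param n_species panel species.
#' @param n_iter permutation iterations per test.
#' @return numeric vector of p-values.
#' @export
experiment_permutation_calibration <- function(n_seeds = 200L, seed0 = 500L,
                                               n_universe = 2000L,
                                               n_species = 10L, n_iter = 1000L) {
  vapply(seq_len(n_seeds), function(k) {
    set.seed(seed0 + k)
    universe <- seq_len(n_universe)
    sets <- lapply(seq_len(n_species), function(s) {
      list(k4 = sample(universe, round(stats::runif(1, 0.45, 0.75) * n_universe)),
           k27 = sample(universe, round(stats::runif(1, 0.45, 0.75) * n_universe)))
    })
    names(sets) <- paste0("s", seq_len(n_species))
    per_sp <- lapply(sets, function(m) unique(c(m$k4, m$k27)))
    observed <- length(Reduce(intersect, per_sp))
    permutation_test_conserved_count(observed, sets, universe, n_iter = n_iter,
                                     seed = seed0 + 10000L + k)$p
  }, numeric(1))
}

#' False-discovery-rate calibration of the repeat-enrichment test
#'
#' Null simulations: foreground counts drawn at the background rates; every
#' BH discovery is false, so the realized FDR is the mean fraction of
#' discovered units per simulation.
#'
#' @param n_sims simulations.
#' @param n_fam repeat families per simulation.
#' @param fg_total,bg_total foreground/background element counts.
#' @param seed integer seed.
#' @param alpha BH level.
#' @return list: `fdr` (realized), `se` (its standard error), `n_sims`.
#' @export
experiment_fdr_calibration <- function(n_sims = 500L, n_fam = 50L,
                                       fg_total = 400L, bg_total = 4000L,
                                       seed = 1L, alpha = 0.05) {
  set.seed(seed)
  per_sim <- vapply(seq_len(n_sims), function(s) {
    rates <- stats::runif(n_fam, 0.01, 0.25)
    bg <- stats::rbinom(n_fam, bg_total, rates)
    fg <- stats::rbinom(n_fam, fg_total, bg / bg_total)
    names(fg) <- names(bg) <- paste0("f", seq_len(n_fam))
    res <- repeat_enrichment(fg, fg_total, bg, bg_total)
    r <- sum(res$q < alpha)
    if (r == 0) 0 else 1   # all discoveries are false under the null
  }, numeric(1))
  list(fdr = mean(per_sim), se = stats::sd(per_sim) / sqrt(n_sims),
       n_sims = n_sims)
}
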