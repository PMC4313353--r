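#' Run the full comparative-regulation pipeline
#'
#' Orchestrates simulate -> consensus -> conservation -> turnover ->
#' conserved sets -> age/repeats -> gene association -> regression from one
#' configuration, writing each stage's tables under `outdir` and a versioned
#' manifest (parameters, file checksums, stage timings). Re-running with the
#' same configuration and seed reproduces all outputs byte-identically
#' (timings live only in the manifest).
#'
#' @param config list (or YAML file path) with fields: `seed` (required),
#'   `outdir` (required), `sim` (list of [sim_config()] overrides), optional
#'   `min_overlap`, `min_replicates`, `n_perm`, `stages` (subset of stage
#'   names; later stages reuse cached tables in `outdir` when their inputs
#'   are not recomputed in this run).
#' @return invisible list: `manifest` and in-memory stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(!is.null(config$seed), !is.null(config$outdir))
  all_stages <- c("simulate", "consensus", "conservation", "turnover",
                  "conserved_sets", "age_repeats", "gene_assoc", "regression")
  stages <- config$stages %||% all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  min_ov <- config$min_overlap %||% 0.5
  min_rep <- config$min_replicates %||% 2L
  n_perm <- config$n_perm %||% 1000L
  panel <- config$panel %||% NULL

  state <- new.env(parent = emptyenv())
  timings <- list()
  files <- character()
  emit <- function(x, name) {
    f <- file.path(outdir, name)
    data.table::fwrite(data.table::as.data.table(x), f, sep = "\t")
    files <<- c(files, f)
    f
  }
  run_stage <- function(name, fn) {
    if (!name %in% stages) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    fn()
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    message("stage ", name, " done (", timings[[name]], "s)")
  }
  need_world <- function() {
    # deterministic regeneration when a later stage runs without `simulate`
    if (is.null(state$world)) {
      state$world <- simulate_world(do.call(sim_config, c(list(seed = config$seed),
                                                          config$sim)))
      state$panel <- panel %||% default_world_panel(state$world)
    }
    state$world
  }
  need_cons <- function() {
    if (is.null(state$cons)) state$cons <- consensus_all(need_world(), min_rep, min_ov)
    state$cons
  }
  need_profile <- function(ref) {
    if (is.null(state$profiles)) state$profiles <- list()
    if (is.null(state$profiles[[ref]])) {
      w <- need_world(); cons <- need_cons()
      others <- setdiff(w$species, ref)
      maps <- lapply(others, function(s) orthology_map(w, ref, s))
      names(maps) <- others
      targets <- lapply(others, function(s) list(k4 = cons[[s]]$k4, k27 = cons[[s]]$k27))
      names(targets) <- others
      state$profiles[[ref]] <- conservation_profile(cons[[ref]]$elements, maps,
                                                    targets, min_ov)
    }
    state$profiles[[ref]]
  }

  run_stage("simulate", function() {
    w <- need_world()
    counts <- data.table::as.data.table(w$elements)[, list(n = .N), by = class]
    emit(counts, "true_element_counts.tsv")
  })

  run_stage("consensus", function() {
    w <- need_world(); cons <- need_cons()
    funnel <- data.table::rbindlist(lapply(w$species, function(sp) {
      data.table::data.table(
        species = sp,
        n_peaks = sum(w$peaks$species == sp),
        n_k4_consensus = nrow(cons[[sp]]$k4),
        n_k27_consensus = nrow(cons[[sp]]$k27),
        n_promoter_dual = sum(cons[[sp]]$elements$class == "promoter_dual"),
        n_promoter_k4 = sum(cons[[sp]]$elements$class == "promoter_k4"),
        n_enhancer = sum(cons[[sp]]$elements$class == "enhancer"))
    }))
    emit(funnel, "consensus_funnel.tsv")
    emit(cons[[w$anchor]]$elements, "anchor_elements.tsv")
  })

  run_stage("conservation", function() {
    w <- need_world()
    pr <- need_profile(w$anchor)
    emit(pr$profile, "anchor_conservation_profile.tsv")
    cons <- need_cons()
    mats <- conservation_ratio_matrices(w, cons, min_overlap = min_ov)
    for (cg in names(mats)) {
      m <- mats[[cg]]
      state[[paste0("ratios_", cg)]] <- m
      emit(data.table::data.table(species = rownames(m), m),
           sprintf("ratios_%s.tsv", cg))
    }
  })

  run_stage("turnover", function() {
    fits <- list()
    for (cg in c("promoter", "enhancer")) {
      m <- state[[paste0("ratios_", cg)]]
      if (is.null(m)) {
        f <- file.path(outdir, sprintf("ratios_%s.tsv", cg))
        if (!file.exists(f)) stop("turnover stage: missing cached ratio matrix ", f)
        x <- data.table::fread(f)
        m <- as.matrix(x[, -1]); rownames(m) <- x$species
      }
      tr <- if (!is.null(state$world)) state$world$tree else mammal_tree()
      fit <- fit_exponential_decay(decay_points(m, tr))
      fits[[cg]] <- data.table::data.table(
        class = cg, half_life = fit$half_life,
        ci_lo = fit$ci95_half_life[1], ci_hi = fit$ci95_half_life[2],
        mean_lifetime = mean_lifetime(fit$half_life), r2 = fit$r_squared,
        n_pairs = fit$n)
      nj <- nj_tree(1 - m)
      f <- file.path(outdir, sprintf("nj_%s.nwk", cg))
      ape::write.tree(nj, f)
      files <<- c(files, f)
    }
    emit(data.table::rbindlist(fits), "decay_fits.tsv")
  })

  run_stage("conserved_sets", function() {
    w <- need_world(); cons <- need_cons()
    pan <- state$panel %||% default_world_panel(w)
    pr <- need_profile(w$anchor)
    hc <- find_highly_conserved(cons[[w$anchor]]$elements, pr$states, pan)
    emit(hc, "highly_conserved.tsv")
    # permutation null over the required panel, per species and mark
    el_ids <- cons[[w$anchor]]$elements$name
    sets <- lapply(pan$required, function(s) {
      list(H3K4me3 = el_ids[pr$states[, s] %in% c("dual", "k4_only")],
           H3K27ac = el_ids[pr$states[, s] %in% c("dual", "k27_only")])
    })
    names(sets) <- pan$required
    pt <- permutation_test_conserved_count(nrow(hc), sets, el_ids,
                                           n_iter = n_perm, seed = config$seed)
    emit(data.table::data.table(observed = pt$observed, p = pt$p,
                                p_label = pt$p_label, null_mean = pt$null_mean,
                                null_sd = pt$null_sd, n_iter = pt$n_iter),
         "permutation_test.tsv")
    rec <- find_recently_evolved(cons[[w$anchor]]$elements, pr$calls)
    emit(rec, "recently_evolved.tsv")
    state$recent <- rec
    ls <- data.table::rbindlist(lapply(names(pan$clades), function(cn) {
      cl <- pan$clades[[cn]]
      prr <- need_profile(cl$reference)
      x <- find_lineage_specific(cons[[cl$reference]]$elements, prr$calls,
                                 prr$states, cl)
      if (nrow(x)) x[, clade := cn]
      x
    }), fill = TRUE)
    emit(ls, "lineage_specific.tsv")
  })

  run_stage("age_repeats", function() {
    w <- need_world(); cons <- need_cons()
    pr <- need_profile(w$anchor)
    rec <- state$recent
    if (is.null(rec)) rec <- find_recently_evolved(cons[[w$anchor]]$elements, pr$calls)
    ages <- sequence_ages(pr$calls, w$tree, w$anchor)
    ages <- cbind(data.table::data.table(name = cons[[w$anchor]]$elements$name), ages)
    emit(ages, "sequence_ages.tsv")
    rec_ages <- ages[ages$name %in% rec$name]
    all_el <- cons[[w$anchor]]$elements
    enr <- list()
    for (cls in c("promoter", "enhancer")) {
      fg_el <- rec[if (cls == "enhancer") rec$assigned_class == "enhancer"
                   else rec$assigned_class == "promoter"]
      bg_el <- all_el[if (cls == "enhancer") all_el$class == "enhancer"
                      else all_el$class != "enhancer"]
      if (nrow(fg_el) == 0 || nrow(bg_el) == 0) next
      fg <- repeat_overlap_counts(fg_el, w$repeats, min_ov)$family
      bg <- repeat_overlap_counts(bg_el, w$repeats, min_ov)$family
      e <- repeat_enrichment(stats::setNames(fg$count, fg$unit), nrow(fg_el),
                             stats::setNames(bg$count, bg$unit), nrow(bg_el))
      e[, class := cls]
      enr[[cls]] <- e
    }
    emit(data.table::rbindlist(enr), "repeat_enrichment.tsv")
  })

  run_stage("gene_assoc", function() {
    w <- need_world(); cons <- need_cons()
    pr <- need_profile(w$anchor)
    gm <- build_regulatory_domains(w$genes, world_chrom_lengths(w, w$anchor))
    state$gene_models <- gm
    el <- cons[[w$anchor]]$elements
    assoc <- associate_elements(el, gm)
    emit(assoc$links, "element_gene_links.tsv")
    liv <- tsps_and_liver_specific(w$expr, w$config$tissues[1])
    emit(liv, "tissue_specific_genes.tsv")
    rec <- state$recent
    if (is.null(rec)) rec <- find_recently_evolved(el, pr$calls)
    enh_links <- assoc$links[assoc$links$name %in% el$name[el$class == "enhancer"]]
    rec_links <- enh_links[enh_links$name %in% rec$name[rec$assigned_class == "enhancer"]]
    pt <- psg_enrichment(rec_links, enh_links, w$genes$gene_id, w$psg)
    emit(pt, "psg_tests.tsv")
    ratio <- expression_ratio_profile(
      unique(rec_links$gene_id), unique(assoc$links$gene_id), w$expr)
    emit(data.table::data.table(tissue = names(ratio), ratio = ratio),
         "expression_ratios.tsv")
  })

  run_stage("regression", function() {
    w <- need_world(); cons <- need_cons()
    pr <- need_profile(w$anchor)
    gm <- state$gene_models
    if (is.null(gm)) gm <- build_regulatory_domains(w$genes, world_chrom_lengths(w, w$anchor))
    tab <- feature_table(w, cons[[w$anchor]]$elements, pr, gm)
    ord <- c("reproducibility", "intensity", "length", "tss_dist", "gc",
             "constraint", "tfbs")
    vd <- incremental_r2(tab, ord)
    emit(data.table::data.table(feature = vd$features,
                                marginal_r2 = vd$marginal_r2,
                                cumulative_r2 = vd$cumulative_r2),
         "variance_decomposition.tsv")
  })

  sim_par <- config$sim
  if (!is.null(sim_par$tree)) sim_par$tree <- ape::write.tree(sim_par$tree)
  manifest <- list(
    parameters = list(seed = config$seed, min_overlap = min_ov,
                      min_replicates = min_rep, n_perm = n_perm,
                      sim = sim_par, stages = stages),
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    sub(paste0("^", outdir, "/?"), "", files))),
    timings = timings)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(manifest = manifest, state = state))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# panel for arbitrary worlds: the bundled default when all its species are
# present, otherwise all non-anchor species required and no clades
default_world_panel <- function(world) {
  pan <- default_panel()
  if (world$anchor == pan$anchor &&
      all(c(pan$required, unlist(lapply(pan$clades, `[[`, "members"))) %in%
            world$species)) {
    return(pan)
  }
  species_panel(world$anchor, setdiff(world$species, world$anchor))
}
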