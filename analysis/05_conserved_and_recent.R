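# Highly conserved elements (enriched across the full high-quality panel),
# the permutation null for their count, lineage-specific elements per study
# clade, and recently evolved elements in the anchor species.

source("analysis/00_common.R")

w <- get_world()
cons <- get_cons()
pan <- default_panel()
pr <- get_profile(pan$anchor)
el <- cons[[pan$anchor]]$elements

hc <- find_highly_conserved(el, pr$states, pan)
write_result(hc, "highly_conserved.tsv")
cat(sprintf("%d highly conserved elements (%.0f%% of %d anchor elements); %.0f%% classed promoter\n",
            nrow(hc), 100 * nrow(hc) / nrow(el), nrow(el),
            100 * mean(hc$assigned_class == "promoter")))

sets <- lapply(pan$required, function(s) {
  list(H3K4me3 = el$name[pr$states[, s] %in% c("dual", "k4_only")],
       H3K27ac = el$name[pr$states[, s] %in% c("dual", "k27_only")])
})
names(sets) <- pan$required
pt <- permutation_test_conserved_count(nrow(hc), sets, el$name,
                                       n_iter = 10000, seed = STUDY_SEED)
cat(sprintf("permutation test: observed %d vs null %.1f +- %.1f, p %s\n",
            pt$observed, pt$null_mean, pt$null_sd, pt$p_label))
write_result(data.table::data.table(observed = pt$observed, p = pt$p,
                                    p_label = pt$p_label,
                                    null_mean = pt$null_mean,
                                    null_sd = pt$null_sd, n_iter = pt$n_iter),
             "permutation_test.tsv")

ls_all <- list()
for (cn in names(pan$clades)) {
  cl <- pan$clades[[cn]]
  prr <- get_profile(cl$reference)
  x <- find_lineage_specific(cons[[cl$reference]]$elements, prr$calls,
                             prr$states, cl)
  if (nrow(x)) x$clade <- cn
  ls_all[[cn]] <- x
  cat(sprintf("%s (ref %s): %d lineage-specific elements\n",
              cn, cl$reference, nrow(x)))
}
write_result(data.table::rbindlist(ls_all, fill = TRUE), "lineage_specific.tsv")

rec <- find_recently_evolved(el, pr$calls)
write_result(rec, "recently_evolved.tsv")
cat(sprintf("%d recently evolved elements in %s (%.0f%% enhancers)\n",
            nrow(rec), pan$anchor,
            100 * mean(rec$assigned_class == "enhancer")))
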