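# Anchor-centric conservation: project every human element to the 19 other
# genomes, call conserved/absent/unalignable, and summarise alignability vs
# conservation; then the full pairwise reciprocal conservation-ratio
# matrices for promoters and enhancers.

source("analysis/00_common.R")

w <- get_world()
cons <- get_cons()
pr <- get_profile("human")

write_result(pr$profile, "anchor_conservation_profile.tsv")

# 2-D alignability x conservation histogram per class group
prof <- data.table::as.data.table(pr$profile)
prof[, group := ifelse(class == "enhancer", "enhancer", "promoter")]
h2d <- prof[, .N, by = .(group, n_alignable, n_conserved)]
write_result(h2d[order(group, n_alignable, n_conserved)],
             "alignability_vs_conservation.tsv")

cat(sprintf("promoters: mean conservation ratio %.2f; enhancers: %.2f\n",
            mean(prof$ratio[prof$group == "promoter"], na.rm = TRUE),
            mean(prof$ratio[prof$group == "enhancer"], na.rm = TRUE)))

# coverage-based false-negative check on absent calls
fn <- coverage_false_negative_fraction(w$coverage$absent, w$coverage$control)
cat(sprintf("read-coverage check: %.1f%% of absent calls sit in the control upper tail\n",
            100 * fn))
write_result(data.table::data.table(false_negative_fraction = fn),
             "absent_call_coverage_check.tsv")

mats <- cache("ratio_matrices",
              conservation_ratio_matrices(w, cons))
for (g in names(mats)) {
  m <- mats[[g]]
  write_result(data.table::data.table(species = rownames(m), m),
               sprintf("ratios_%s.tsv", g))
}
cat("pairwise reciprocal conservation-ratio matrices written for both classes\n")
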