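# Sequence ages of recently evolved elements (exaptation analysis: most
# arise from ancestral DNA) and repeat-family enrichment against all
# elements of the same class, binomial test with BH correction.

source("analysis/00_common.R")

w <- get_world()
cons <- get_cons()
pr <- get_profile("human")
el <- cons$human$elements
rec <- find_recently_evolved(el, pr$calls)

ages <- sequence_ages(pr$calls, w$tree, "human")
ages <- cbind(data.table::data.table(name = el$name), ages)
write_result(ages, "sequence_ages.tsv")

rec_ages <- ages[ages$name %in% rec$name]
tab <- table(rec_ages$category)
cat("sequence-age categories of recently evolved elements:\n")
print(tab)
cat(sprintf("=> %.0f%% of recent elements re-use DNA older than 100 Ma (exaptation)\n",
            100 * mean(rec_ages$category == "ancestral")))

enr_all <- list()
for (cls in c("promoter", "enhancer")) {
  fg_el <- rec[rec$assigned_class == cls]
  bg_el <- if (cls == "enhancer") el[el$class == "enhancer"] else
    el[el$class != "enhancer"]
  if (nrow(fg_el) == 0) next
  fg <- repeat_overlap_counts(fg_el, w$repeats)$family
  bg <- repeat_overlap_counts(bg_el, w$repeats)$family
  e <- repeat_enrichment(stats::setNames(fg$count, fg$unit), nrow(fg_el),
                         stats::setNames(bg$count, bg$unit), nrow(bg_el))
  e$class <- cls
  enr_all[[cls]] <- e
  sig <- e[e$q < 0.05 & e$fold > 1]
  cat(sprintf("%s: %d/%d families enriched at q < 0.05 (%s)\n",
              cls, nrow(sig), nrow(e),
              paste(sig$unit, collapse = ", ")))
}
write_result(data.table::rbindlist(enr_all), "repeat_enrichment.tsv")
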