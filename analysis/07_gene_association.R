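# GREAT-style gene association: regulatory domains, element-gene links,
# liver-specific genes from tissue-specificity scores, expression ratios,
# and the three PSG-association tests on recently evolved enhancers.

source("analysis/00_common.R")

w <- get_world()
cons <- get_cons()
pr <- get_profile("human")
el <- cons$human$elements

gm <- build_regulatory_domains(w$genes, world_chrom_lengths(w, "human"))
assoc <- associate_elements(el, gm)
write_result(assoc$links, "element_gene_links.tsv")
cat(sprintf("%d element-gene links over %d genes (median |TSS distance| %.0f kb)\n",
            nrow(assoc$links), length(unique(assoc$links$gene_id)),
            median(abs(assoc$tss_distance$distance), na.rm = TRUE) / 1e3))

liv <- tsps_and_liver_specific(w$expr, w$config$tissues[1])
write_result(liv, "tissue_specific_genes.tsv")
cat(sprintf("%d liver-specific genes (tsps > 1.5, liver argmax, RPKM > 10)\n",
            sum(liv$selected)))

rec <- find_recently_evolved(el, pr$calls)
enh_links <- assoc$links[assoc$links$name %in% el$name[el$class == "enhancer"]]
rec_links <- enh_links[enh_links$name %in%
                         rec$name[rec$assigned_class == "enhancer"]]
pt <- psg_enrichment(rec_links, enh_links, w$genes$gene_id, w$psg)
write_result(pt, "psg_tests.tsv")
cat("PSG association tests (uncorrected):\n")
print(pt[, c("test", "p")])

ratio <- expression_ratio_profile(unique(rec_links$gene_id),
                                  unique(assoc$links$gene_id), w$expr)
write_result(data.table::data.table(tissue = names(ratio), ratio = ratio),
             "expression_ratios_recent_enhancers.tsv")
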