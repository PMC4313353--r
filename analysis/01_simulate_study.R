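# Generate the synthetic 20-mammal liver study: dated tree, orthologous DNA
# blocks with turnover, true promoter/enhancer histories, replicate peak
# calls, repeats, genes, expression and PSGs — with full ground truth.

source("analysis/00_common.R")

w <- get_world()
print(w)

counts <- data.table::as.data.table(w$elements)[, .(n_true = .N), by = class]
write_result(counts, "true_element_counts.tsv")

per_sp <- data.table::data.table(
  species = w$species,
  n_active = colSums(w$active),
  n_blocks = colSums(w$block_presence),
  n_replicates = ifelse(w$species %in% w$config$single_replicate_species,
                        1L, w$config$n_replicates))
write_result(per_sp, "true_active_per_species.tsv")

cat(sprintf("\n%d true elements across %d species (%.0f active per species on average);\n",
            nrow(w$elements), length(w$species), mean(colSums(w$active))))
cat(sprintf("planted half-lives: promoters %d Ma, enhancers %d Ma.\n",
            900L, 300L))

# full plain-text fixture emission (peaks, maps, annotations, truth tables)
man <- emit_fixtures(w, file.path(SCRATCH, "fixtures"))
cat(sprintf("emitted %d fixture files under %s/fixtures\n", nrow(man), SCRATCH))
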