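#' Write a synthetic world to plain-text fixture files
#'
#' Emits per-species/mark/replicate peak BEDs (BED6+1, fold enrichment in
#' column 7), orthology-map TSVs for the requested species pairs, the repeat
#' annotation (BED6+2: class, family), gene/expression/PSG tables, the
#' constrained-element BED, the dated tree, truth tables for every element,
#' and a manifest with md5 checksums.
#'
#' @param world a `synth_world`.
#' @param outdir output directory (created if needed).
#' @param map_pairs 2-column matrix/data.frame of species pairs to emit maps
#'   for; default anchor vs every other species.
#' @return data.table manifest (`file`, `md5`), also written to
#'   `manifest.tsv`.
#' @export
emit_fixtures <- function(world, outdir, map_pairs = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("peaks", "maps", "truth")) {
    dir.create(file.path(outdir, d), showWarnings = FALSE)
  }
  files <- character()
  add <- function(f) files <<- c(files, f)

  f <- file.path(outdir, "tree.nwk")
  ape::write.tree(world$tree, f); add(f)

  pk <- world$peaks
  for (sp in unique(pk$species)) for (m in unique(pk$mark)) {
    sub <- pk[pk$species == sp & pk$mark == m]
    for (r in unique(sub$replicate)) {
      f <- file.path(outdir, "peaks", sprintf("%s_%s_rep%d.bed", sp, m, r))
      write_bed(sub[sub$replicate == r],
                f, cols = c("name", "score", "strand", "fold_enrichment"))
      add(f)
    }
  }

  if (is.null(map_pairs)) {
    others <- setdiff(world$species, world$anchor)
    map_pairs <- cbind(world$anchor, others)
  }
  for (k in seq_len(nrow(map_pairs))) {
    a <- map_pairs[k, 1]; b <- map_pairs[k, 2]
    f <- file.path(outdir, "maps", sprintf("%s__%s.tsv", a, b))
    write_ortho_map(orthology_map(world, a, b), f); add(f)
  }

  f <- file.path(outdir, "repeats.bed")
  write_bed(world$repeats, f, cols = c("name", "score", "strand", "rclass", "family"))
  add(f)
  f <- file.path(outdir, "constrained.bed")
  write_bed(world$constrained, f, cols = character()); add(f)
  f <- file.path(outdir, "genes.tsv")
  data.table::fwrite(world$genes, f, sep = "\t"); add(f)
  f <- file.path(outdir, "expression.tsv")
  data.table::fwrite(data.table::data.table(gene_id = rownames(world$expr),
                                            world$expr), f, sep = "\t")
  add(f)
  f <- file.path(outdir, "psg.txt")
  writeLines(world$psg, f); add(f)

  tru <- data.table::copy(world$elements)
  f <- file.path(outdir, "truth", "elements.tsv")
  data.table::fwrite(tru, f, sep = "\t"); add(f)
  f <- file.path(outdir, "truth", "active.tsv")
  data.table::fwrite(data.table::data.table(id = rownames(world$active),
                                            world$active), f, sep = "\t")
  add(f)
  f <- file.path(outdir, "truth", "blocks.tsv")
  data.table::fwrite(world$blocks, f, sep = "\t"); add(f)

  manifest <- data.table::data.table(
    file = sub(paste0("^", outdir, "/?"), "", files),
    md5 = unname(tools::md5sum(files)))
  data.table::fwrite(manifest, file.path(outdir, "manifest.tsv"), sep = "\t")
  manifest[]
}

#' Read emitted replicate peak files back
#'
#' @param dir fixture directory written by [emit_fixtures()].
#' @return combined peak data.table (`species`, `mark`, `replicate` parsed
#'   from file names).
#' @export
load_peak_fixtures <- function(dir) {
  fs <- list.files(file.path(dir, "peaks"), full.names = TRUE)
  out <- lapply(fs, function(f) {
    m <- regmatches(basename(f),
                    regexec("^(.*)_(H3K4me3|H3K27ac)_rep(\\d+)\\.bed$", basename(f)))[[1]]
    x <- read_bed(f, species = m[2], extra_cols = "fold_enrichment")
    x[, `:=`(mark = m[3], replicate = as.integer(m[4]))]
    x
  })
  pk <- data.table::rbindlist(out)
  data.table::setorder(pk, species, mark, replicate, chrom, start)
  pk[]
}
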