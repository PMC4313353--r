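#' GREAT-style gene regulatory domains
#'
#' Each gene gets a basal domain (TSS -5 kb / +1 kb, strand-oriented) and an
#' extension on each side reaching the nearest neighbouring gene's basal
#' domain, capped at 1 Mb beyond the basal edge and clipped to the
#' chromosome; the basal domain is always included.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `tss`, `strand`.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param basal_up,basal_down basal extent upstream/downstream of the TSS.
#' @param max_extension cap beyond the basal edge, per side.
#' @return data.table: `gene_id`, `chrom`, `tss`, `strand`, `basal_start`,
#'   `basal_end`, `dom_start`, `dom_end`.
#' @export
build_regulatory_domains <- function(genes, chrom_lengths,
                                     basal_up = 5000, basal_down = 1000,
                                     max_extension = 1e6) {
  g <- data.table::as.data.table(genes)
  stopifnot(all(c("gene_id", "chrom", "tss", "strand") %in% names(g)))
  stopifnot(all(g$chrom %in% names(chrom_lengths)))
  g <- data.table::copy(g)
  g[, basal_start := ifelse(strand == "+", tss - basal_up, tss - basal_down)]
  g[, basal_end := ifelse(strand == "+", tss + basal_down, tss + basal_up)]
  clen <- chrom_lengths[g$chrom]
  if (any(g$basal_start < 0 | g$basal_end > clen)) {
    warning("basal domain(s) clipped to chromosome bounds")
  }
  g[, basal_start := pmax(0, basal_start)]
  g[, basal_end := pmin(clen, basal_end)]
  data.table::setorder(g, chrom, tss)
  g[, `:=`(dom_start = NA_real_, dom_end = NA_real_)]
  for (ch in unique(g$chrom)) {
    i <- which(g$chrom == ch)
    bs <- g$basal_start[i]; be <- g$basal_end[i]
    n <- length(i)
    left_nb <- if (n > 1) c(-Inf, cummax(be[-n])) else -Inf
    right_nb <- if (n > 1) c(rev(cummin(rev(bs[-1]))), Inf) else Inf
    ds <- pmin(bs, pmax(left_nb, bs - max_extension))
    de <- pmax(be, pmin(right_nb, be + max_extension))
    g$dom_start[i] <- pmax(0, ds)
    g$dom_end[i] <- pmin(chrom_lengths[ch], de)
  }
  g[]
}

#' Associate elements with gene regulatory domains
#'
#' An element is linked to every gene whose regulatory domain it overlaps by
#' at least one base; also returns the signed distance from the element
#' midpoint to the nearest TSS (negative = upstream of the gene, by its
#' strand).
#'
#' @param elements classified consensus elements (with `name`).
#' @param gene_models output of [build_regulatory_domains()].
#' @return list: `links` (data.table `name`, `gene_id`) and `tss_distance`
#'   (data.table `name`, `gene_id`, `distance`).
#' @export
associate_elements <- function(elements, gene_models) {
  el <- data.table::as.data.table(elements)
  gm <- data.table::as.data.table(gene_models)
  doms <- data.table::data.table(species = el$species[1], chrom = gm$chrom,
                                 start = gm$dom_start, end = gm$dom_end)
  ov <- interval_overlaps(el, doms)
  links <- data.table::data.table(name = el$name[ov$i], gene_id = gm$gene_id[ov$j])
  mid <- (el$start + el$end) / 2
  nearest <- vapply(seq_len(nrow(el)), function(k) {
    same <- which(gm$chrom == el$chrom[k])
    if (!length(same)) return(NA_integer_)
    same[which.min(abs(gm$tss[same] - mid[k]))]
  }, integer(1))
  sgn <- ifelse(gm$strand[nearest] == "+", 1, -1)
  tssd <- data.table::data.table(name = el$name,
                                 gene_id = gm$gene_id[nearest],
                                 distance = sgn * (mid - gm$tss[nearest]))
  list(links = unique(links), tss_distance = tssd)
}

#' Tissue-specificity scores and target-tissue-specific genes
#'
#' `tsps(g)` is the target-tissue expression over the mean expression of the
#' other tissues (missing measurements imputed as 0). A gene is selected as
#' target-tissue specific when its tsps exceeds `tsps_min`, the target
#' tissue is its expression argmax, and target expression exceeds
#' `rpkm_min`.
#'
#' @param expr genes x tissues RPKM matrix (rownames = gene ids).
#' @param target_tissue column name of the target tissue.
#' @param tsps_min,rpkm_min selection thresholds.
#' @return data.table: `gene_id`, `tsps`, `argmax_target`, `selected`.
#' @export
tsps_and_liver_specific <- function(expr, target_tissue = "liver",
                                    tsps_min = 1.5, rpkm_min = 10) {
  stopifnot(target_tissue %in% colnames(expr), ncol(expr) >= 2)
  expr[is.na(expr)] <- 0
  x <- expr[, target_tissue]
  others <- rowMeans(expr[, setdiff(colnames(expr), target_tissue), drop = FALSE])
  tsps <- ifelse(x == 0 & others == 0, 0, x / others)
  am <- colnames(expr)[max.col(expr, ties.method = "first")]
  argmax_target <- am == target_tissue & x > 0
  data.table::data.table(gene_id = rownames(expr), tsps = tsps,
                         argmax_target = argmax_target,
                         selected = tsps > tsps_min & argmax_target & x > rpkm_min)
}

#' Binomial gene-set enrichment over element-linked genes
#'
#' Per annotation term: one-sided upper-tail binomial test of the foreground
#' hit fraction against the background fraction, BH-corrected across terms;
#' terms pass when `q < q_max` and fold enrichment exceeds `fold_min`.
#'
#' @param fg_genes,bg_genes character vectors of genes linked to the
#'   foreground / background element sets.
#' @param annotation_sets named list of gene-id vectors.
#' @param q_max,fold_min reporting thresholds.
#' @return data.table: `term`, `fg_count`, `fg_total`, `bg_count`,
#'   `bg_total`, `fold`, `p`, `q`, `reported`.
#' @export
geneset_enrichment_binomial <- function(fg_genes, bg_genes, annotation_sets,
                                        q_max = 0.05, fold_min = 2) {
  if (!length(bg_genes)) stop("empty background gene set")
  fg_genes <- unique(fg_genes); bg_genes <- unique(bg_genes)
  n_fg <- length(fg_genes); n_bg <- length(bg_genes)
  res <- data.table::rbindlist(lapply(names(annotation_sets), function(term) {
    k <- sum(fg_genes %in% annotation_sets[[term]])
    K <- sum(bg_genes %in% annotation_sets[[term]])
    rate <- K / n_bg
    p <- if (rate == 0) 1 else stats::pbinom(k - 1, n_fg, rate, lower.tail = FALSE)
    data.table::data.table(term = term, fg_count = k, fg_total = n_fg,
                           bg_count = K, bg_total = n_bg,
                           fold = if (rate > 0) (k / n_fg) / rate else NA_real_,
                           p = p)
  }))
  res[, q := stats::p.adjust(p, "BH")]
  res[, reported := q < q_max & !is.na(fold) & fold > fold_min]
  res[]
}

#' Enrichment of recently evolved enhancers near positively selected genes
#'
#' Three complementary tests, reported uncorrected:
#' (i) hypergeometric on enhancer-gene links: are recently evolved enhancers
#' over-represented among links to PSG regulatory domains;
#' (ii) hypergeometric on genes: are PSGs more likely than other genes to
#' harbour at least one recent enhancer;
#' (iii) one-sided Wilcoxon rank-sum on the per-gene proportion of recent
#' enhancers among its enhancers (genes with at least one enhancer), PSG vs
#' non-PSG.
#'
#' @param recent_links links (from [associate_elements()]) of recently
#'   evolved enhancers; must be a subset of `all_links` elements.
#' @param all_links links of all enhancers (the background).
#' @param gene_universe character vector of all gene ids.
#' @param psg_list character vector of positively selected gene ids.
#' @return data.table with one row per test: `test`, `statistic`, `p`,
#'   `k`, `n`, `K`, `N`.
#' @export
psg_enrichment <- function(recent_links, all_links, gene_universe, psg_list) {
  if (!length(psg_list)) stop("empty PSG list")
  stopifnot(all(psg_list %in% gene_universe))
  rl <- data.table::as.data.table(recent_links)
  al <- data.table::as.data.table(all_links)
  # (i) link-level hypergeometric
  N1 <- nrow(al); K1 <- sum(al$gene_id %in% psg_list)
  n1 <- nrow(rl); k1 <- sum(rl$gene_id %in% psg_list)
  p1 <- stats::phyper(k1 - 1, K1, N1 - K1, n1, lower.tail = FALSE)
  # (ii) gene-level hypergeometric
  genes_recent <- unique(rl$gene_id)
  N2 <- length(gene_universe); K2 <- length(psg_list)
  n2 <- length(genes_recent); k2 <- sum(genes_recent %in% psg_list)
  p2 <- stats::phyper(k2 - 1, K2, N2 - K2, n2, lower.tail = FALSE)
  # (iii) per-gene proportion Wilcoxon (genes with >= 1 enhancer)
  tot <- al[, list(n_total = .N), by = gene_id]
  rec <- rl[, list(n_recent = .N), by = gene_id]
  tab <- merge(tot, rec, by = "gene_id", all.x = TRUE)
  tab[is.na(n_recent), n_recent := 0L]
  tab[, prop := n_recent / n_total]
  is_psg <- tab$gene_id %in% psg_list
  if (any(is_psg) && any(!is_psg)) {
    wt <- stats::wilcox.test(tab$prop[is_psg], tab$prop[!is_psg],
                             alternative = "greater", exact = FALSE)
    p3 <- wt$p.value; stat3 <- unname(wt$statistic)
  } else {
    p3 <- NA_real_; stat3 <- NA_real_
  }
  data.table::data.table(
    test = c("links_in_psg_domains", "psg_with_recent_enhancer",
             "psg_proportion_wilcoxon"),
    statistic = c(k1, k2, stat3),
    p = c(p1, p2, p3),
    k = c(k1, k2, NA), n = c(n1, n2, NA), K = c(K1, K2, NA), N = c(N1, N2, NA))
}

#' Per-tissue expression ratio of a gene set over a background set
#'
#' Mean RPKM (0-imputed) of set-linked genes divided by the background mean,
#' per tissue; tissues with zero background mean are NA.
#'
#' @param set_genes,background_genes character vectors of gene ids.
#' @param expr genes x tissues RPKM matrix.
#' @return named numeric vector of ratios per tissue.
#' @export
expression_ratio_profile <- function(set_genes, background_genes, expr) {
  stopifnot(length(set_genes) > 0, length(background_genes) > 0)
  expr[is.na(expr)] <- 0
  sg <- intersect(set_genes, rownames(expr))
  bgg <- intersect(background_genes, rownames(expr))
  num <- if (length(sg)) colMeans(expr[sg, , drop = FALSE]) else
    stats::setNames(rep(0, ncol(expr)), colnames(expr))
  den <- colMeans(expr[bgg, , drop = FALSE])
  ifelse(den > 0, num / den, NA_real_)
}
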