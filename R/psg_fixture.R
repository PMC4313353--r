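#' Gene-level fixture for PSG-association power and calibration
#'
#' A compact generator for the positively-selected-gene analysis alone:
#' genes with GREAT-style regulatory domains on one chromosome, a random PSG
#' subset, and enhancers of which a fraction are recently evolved. Recent
#' enhancers are placed with `assoc`-fold higher rate inside PSG regulatory
#' domains (rejection sampling); `assoc = 1` is the null.
#'
#' @param seed integer seed.
#' @param n_genes,chrom_len,n_enh,frac_recent,n_psg fixture scale.
#' @param assoc fold-rate of recent enhancers inside PSG domains.
#' @param enh_len enhancer length (bp).
#' @return list: `elements` (with `recent` flag), `genes`, `domains`, `psg`,
#'   `chrom_len`.
#' @export
simulate_psg_fixture <- function(seed = 1L, n_genes = 300L, chrom_len = 3e7,
                                 n_enh = 600L, frac_recent = 0.25,
                                 n_psg = 30L, assoc = 3, enh_len = 1500L) {
  set.seed(seed)
  genes <- data.table::data.table(
    gene_id = sprintf("g%04d", seq_len(n_genes)),
    chrom = "chr1",
    tss = sort(round(stats::runif(n_genes, 1e4, chrom_len - 1e4))),
    strand = sample(c("+", "-"), n_genes, TRUE))
  dom <- build_regulatory_domains(genes, c(chr1 = chrom_len))
  psg <- sort(sample(genes$gene_id, n_psg))
  pd <- dom[dom$gene_id %in% psg, ]
  in_psg_dom <- function(pos) {
    out <- rep(FALSE, length(pos))
    for (k in seq_len(nrow(pd))) {
      out <- out | (pos >= pd$dom_start[k] & pos < pd$dom_end[k])
    }
    out
  }
  n_recent <- round(frac_recent * n_enh)
  draw <- function(n, weight_psg) {
    pos <- numeric(0)
    while (length(pos) < n) {
      cand <- stats::runif(3 * n, 0, chrom_len - enh_len)
      acc <- ifelse(in_psg_dom(cand + enh_len / 2), weight_psg, 1) / max(weight_psg, 1)
      pos <- c(pos, cand[stats::runif(length(cand)) < acc])
    }
    round(pos[seq_len(n)])
  }
  st <- c(draw(n_recent, assoc), draw(n_enh - n_recent, 1))
  elements <- data.table::data.table(
    species = "ref", chrom = "chr1", start = st, end = st + enh_len,
    name = sprintf("enh%05d", seq_len(n_enh)), class = "enhancer",
    recent = rep(c(TRUE, FALSE), c(n_recent, n_enh - n_recent)))
  list(elements = elements, genes = genes, domains = dom, psg = psg,
       chrom_len = chrom_len)
}

#' Run the three PSG tests on a PSG fixture
#'
#' @param fx output of [simulate_psg_fixture()].
#' @return [psg_enrichment()] result table.
#' @export
psg_fixture_tests <- function(fx) {
  el <- data.table::copy(fx$elements)
  all_links <- associate_elements(el, fx$domains)$links
  rec_links <- all_links[all_links$name %in% el$name[el$recent]]
  psg_enrichment(rec_links, all_links, fx$genes$gene_id, fx$psg)
}
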