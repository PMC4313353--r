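#' Sequence age of elements from cross-species alignability
#'
#' The sequence age of an element is the divergence time of the most
#' distantly related species with a uniquely alignable orthologous sequence;
#' elements alignable nowhere get age 0 (strictly species-specific DNA).
#' Ages bin into young (0-40 Ma), mid (40-100 Ma) and ancestral (>= 100 Ma)
#' DNA.
#'
#' @param calls element-by-species call matrix from [conservation_profile()]
#'   (`conserved`/`absent` rows imply unique alignability; `unalignable`
#'   does not).
#' @param tree dated `phylo`.
#' @param reference reference species (the anchor of the calls).
#' @return data.table with `age` (Ma) and `category`.
#' @export
sequence_ages <- function(calls, tree, reference) {
  sps <- colnames(calls)
  divs <- vapply(sps, function(s) divergence_time(tree, reference, s), numeric(1))
  alignable <- calls != "unalignable"
  age <- apply(alignable, 1, function(a) if (any(a)) max(divs[a]) else 0)
  data.table::data.table(age = age, category = age_category(age))
}

#' @rdname sequence_ages
#' @param age numeric Ma.
#' @param breaks bin edges (lower edges of mid and ancestral).
#' @export
age_category <- function(age, breaks = c(40, 100)) {
  ifelse(age < breaks[1], "young", ifelse(age < breaks[2], "mid", "ancestral"))
}

#' Elements containing repeats, per repeat family
#'
#' A repetitive element is included in a regulatory element when it overlaps
#' it by at least `min_overlap` of the repeat's length; each regulatory
#' element counts at most once per family (and per class).
#'
#' @param elements regulatory element intervals (with `name`).
#' @param repeats repeat annotation intervals with `family` and `rclass`.
#' @param min_overlap required fraction of the repeat length.
#' @return list with `family` and `rclass` data.tables of per-unit element
#'   counts (`unit`, `count`).
#' @export
repeat_overlap_counts <- function(elements, repeats, min_overlap = 0.5) {
  el <- data.table::as.data.table(elements)
  rp <- data.table::as.data.table(repeats)
  ov <- interval_overlaps(rp, el)
  ov <- ov[frac_a >= min_overlap]
  hits <- data.table::data.table(family = rp$family[ov$i],
                                 rclass = rp$rclass[ov$i],
                                 element = el$name[ov$j])
  fam <- unique(hits[, list(family, element)])[, list(count = .N), by = family]
  cls <- unique(hits[, list(rclass, element)])[, list(count = .N), by = rclass]
  data.table::setnames(fam, "family", "unit")
  data.table::setnames(cls, "rclass", "unit")
  list(family = fam[], rclass = cls[])
}

#' Binomial repeat-family enrichment with BH correction
#'
#' One-sided upper-tail binomial test per unit (family or class): foreground
#' hit count out of `fg_total` elements against the background hit rate
#' `bg_count / bg_total`; Benjamini-Hochberg correction across the units of
#' one analysis. A background rate floor of `0.5 / bg_total` replaces an
#' empty background cell (flagged).
#'
#' @param fg_counts named integer vector (per unit) of foreground elements
#'   containing the unit.
#' @param fg_total number of foreground elements.
#' @param bg_counts named integer vector over the same (or wider) units.
#' @param bg_total number of background elements.
#' @return data.table: `unit`, `fg_count`, `fg_total`, `bg_count`,
#'   `bg_total`, `fold`, `p`, `q`, `floored`.
#' @export
repeat_enrichment <- function(fg_counts, fg_total, bg_counts, bg_total) {
  stopifnot(fg_total <= bg_total)
  units <- union(names(fg_counts), names(bg_counts))
  fg <- fg_counts[units]; fg[is.na(fg)] <- 0
  bg <- bg_counts[units]; bg[is.na(bg)] <- 0
  stopifnot(all(fg <= fg_total), all(bg <= bg_total))
  floored <- bg == 0 & fg > 0
  if (any(floored)) warning(sum(floored), " unit(s) with empty background; rate floored")
  rate <- ifelse(bg == 0, 0.5 / bg_total, bg / bg_total)
  p <- stats::pbinom(fg - 1, fg_total, rate, lower.tail = FALSE)
  fold <- (fg / fg_total) / rate
  data.table::data.table(unit = units, fg_count = as.integer(fg),
                         fg_total = fg_total, bg_count = as.integer(bg),
                         bg_total = bg_total, fold = fold, p = p,
                         q = stats::p.adjust(p, "BH"), floored = floored)
}
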