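#' Fraction of element bases under sequence constraint
#'
#' Covered bases of the element intersected with the (merged) constrained
#' annotation, divided by element length.
#'
#' @param elements interval data.frame.
#' @param constrained constrained-element annotation intervals.
#' @return numeric vector, one fraction per element.
#' @export
constraint_fraction <- function(elements, constrained) {
  el <- data.table::as.data.table(elements)
  cons <- merge_interval_set(constrained)
  ov <- interval_overlaps(el, cons)
  cov <- rep(0, nrow(el))
  if (nrow(ov)) {
    agg <- ov[, list(bp = sum(ov)), by = i]
    cov[agg$i] <- agg$bp
  }
  cov / (el$end - el$start)
}

#' Incremental variance decomposition by multiple regression
#'
#' Ordinary least squares of the conservation-ratio response on growing
#' prefixes of the feature list: marginal (univariate) R-squared per
#' feature, cumulative R-squared after adding each feature left to right,
#' and the pairwise R-squared (squared Pearson correlation) matrix between
#' features. Collinear features that add no rank are kept in the table but
#' contribute nothing beyond their predecessors.
#'
#' @param table data.frame holding the response and feature columns.
#' @param feature_order character vector of feature column names, in the
#'   order they are added.
#' @param response response column name (must lie in `[0, 1]`).
#' @return list of class `variance_decomposition`: `features`, `marginal_r2`,
#'   `cumulative_r2`, `full_r2`, `pairwise_r2`.
#' @export
incremental_r2 <- function(table, feature_order, response = "ratio") {
  tb <- data.table::as.data.table(table)
  stopifnot(all(c(response, feature_order) %in% names(tb)),
            nrow(tb) >= length(feature_order) + 2)
  tb <- tb[stats::complete.cases(tb[, c(response, feature_order), with = FALSE])]
  y <- tb[[response]]
  stopifnot(all(y >= 0 & y <= 1))
  const <- vapply(feature_order, function(f) stats::var(tb[[f]]) == 0, logical(1))
  if (any(const)) {
    warning("constant feature(s) dropped: ", paste(feature_order[const], collapse = ", "))
    feature_order <- feature_order[!const]
  }
  r2 <- function(fml) summary(stats::lm(fml, data = tb))$r.squared
  marginal <- vapply(feature_order, function(f) {
    r2(stats::reformulate(f, response))
  }, numeric(1))
  cumulative <- vapply(seq_along(feature_order), function(k) {
    r2(stats::reformulate(feature_order[seq_len(k)], response))
  }, numeric(1))
  pw <- stats::cor(as.matrix(tb[, feature_order, with = FALSE]))^2
  structure(list(features = feature_order, marginal_r2 = marginal,
                 cumulative_r2 = cumulative,
                 full_r2 = cumulative[length(cumulative)],
                 pairwise_r2 = pw),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat("variance decomposition (full model R2 =", round(x$full_r2, 3), ")\n")
  print(data.frame(feature = x$features,
                   marginal_r2 = round(x$marginal_r2, 3),
                   cumulative_r2 = round(x$cumulative_r2, 3)))
  invisible(x)
}

#' Feature table for anchor elements of a synthetic world
#'
#' Assembles the per-element regression table: experimental features from
#' the consensus peaks (reproducibility, intensity, length), distance to
#' the nearest TSS, fixture-supplied GC content and TFBS counts, the
#' constraint fraction from the constrained-element annotation, and the
#' conservation ratio response from the anchor profile.
#'
#' @param world a `synth_world`.
#' @param anchor_elements classified consensus elements of the anchor.
#' @param profile output of [conservation_profile()].
#' @param gene_models output of [build_regulatory_domains()] for the anchor.
#' @return data.table, one row per anchor element with a defined ratio.
#' @export
feature_table <- function(world, anchor_elements, profile, gene_models) {
  el <- data.table::as.data.table(anchor_elements)
  assoc <- associate_elements(el, gene_models)
  tssd <- assoc$tss_distance$distance[match(el$name, assoc$tss_distance$name)]
  # match consensus elements back to true elements for fixture-supplied
  # sequence features (GC, TFBS), by midpoint containment in the truth table
  lay <- world$layouts[[world$anchor]]
  tru <- world$elements[world$active[, world$anchor]]
  ts <- lay$start[match(tru$block_id, lay$block_id)] + tru$offset
  tdt <- data.table::data.table(species = world$anchor, chrom = "chr1",
                                start = ts, end = ts + tru$length,
                                gc = tru$gc, tfbs = tru$tfbs)
  ovt <- interval_overlaps(el, tdt)
  ovt <- ovt[order(-ov)][!duplicated(i)]
  gc <- tfbs <- rep(NA_real_, nrow(el))
  gc[ovt$i] <- tdt$gc[ovt$j]
  tfbs[ovt$i] <- tdt$tfbs[ovt$j]
  tab <- data.table::data.table(
    name = el$name, class = el$class,
    reproducibility = el$reproducibility,
    intensity = el$intensity,
    length = el$end - el$start,
    tss_dist = abs(tssd),
    gc = gc, tfbs = tfbs,
    constraint = constraint_fraction(el, world$constrained),
    ratio = profile$profile$ratio)
  tab[!is.na(ratio) & !is.na(gc)]
}
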