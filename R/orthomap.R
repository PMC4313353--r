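#' Block-wise orthology maps between two genomes
#'
#' An orthology map is a table of paired alignment blocks: equal-length spans
#' in species A and species B, each side non-overlapping within the map,
#' pairing one-to-one. It abstracts a whole-genome alignment down to the
#' coordinate correspondence needed for interval projection.
#'
#' @param x data.frame with columns `species_a`, `chrom_a`, `start_a`,
#'   `end_a`, `strand_a`, `species_b`, `chrom_b`, `start_b`, `end_b`,
#'   `strand_b` (0-based half-open).
#' @return validated `ortho_map` (a data.table).
#' @export
ortho_map <- function(x) {
  m <- data.table::as.data.table(x)
  need <- c("species_a", "chrom_a", "start_a", "end_a", "strand_a",
            "species_b", "chrom_b", "start_b", "end_b", "strand_b")
  stopifnot(all(need %in% names(m)))
  if (any(m$end_a - m$start_a != m$end_b - m$start_b)) {
    stop("malformed map: paired blocks must have equal lengths")
  }
  for (side in c("a", "b")) {
    ch <- m[[paste0("chrom_", side)]]
    s <- m[[paste0("start_", side)]]; e <- m[[paste0("end_", side)]]
    o <- order(ch, s)
    ok <- c(TRUE, ch[o][-1] != ch[o][-length(o)] | s[o][-1] >= e[o][-length(o)])
    if (!all(ok)) stop("malformed map: overlapping blocks on side ", side)
  }
  data.table::setorder(m, chrom_a, start_a)
  class(m) <- c("ortho_map", class(m))
  m[]
}

#' Swap the two sides of an orthology map
#' @param map an `ortho_map`.
#' @return the reversed `ortho_map` (B as query side).
#' @export
flip_map <- function(map) {
  m <- data.table::copy(data.table::as.data.table(map))
  data.table::setnames(m,
    c("species_a", "chrom_a", "start_a", "end_a", "strand_a",
      "species_b", "chrom_b", "start_b", "end_b", "strand_b"),
    c("species_b", "chrom_b", "start_b", "end_b", "strand_b",
      "species_a", "chrom_a", "start_a", "end_a", "strand_a"))
  ortho_map(m)
}

#' Orthology map between two species of a synthetic world
#'
#' Blocks present in both species, with coordinates from each species'
#' genome layout; all pairings are plus-strand.
#'
#' @param world a `synth_world`.
#' @param a,b species ids (query side `a`).
#' @return an `ortho_map`.
#' @export
orthology_map <- function(world, a, b) {
  shared <- which(world$block_presence[, a] & world$block_presence[, b])
  ids <- world$blocks$block_id[shared]
  la <- world$layouts[[a]]; lb <- world$layouts[[b]]
  sa <- la$start[match(ids, la$block_id)]
  sb <- lb$start[match(ids, lb$block_id)]
  L <- world$config$block_length
  o <- order(sa)
  # constructed blocks are disjoint by design; skip re-validation
  m <- data.table::data.table(
    species_a = a, chrom_a = "chr1", start_a = sa[o], end_a = sa[o] + L,
    strand_a = "+",
    species_b = b, chrom_b = "chr1", start_b = sb[o], end_b = sb[o] + L,
    strand_b = "+")
  class(m) <- c("ortho_map", class(m))
  m[]
}

#' @rdname ortho_map
#' @param path TSV file (10 columns, header) to read or write.
#' @export
read_ortho_map <- function(path) ortho_map(data.table::fread(path, sep = "\t"))

#' @rdname ortho_map
#' @param map an `ortho_map` to write.
#' @export
write_ortho_map <- function(map, path) {
  data.table::fwrite(data.table::as.data.table(map), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Project intervals through an orthology map
#'
#' Each query interval is intersected with the map's A-side blocks and mapped
#' affinely within each block. The projection is `unmapped` when no block
#' overlaps the query; `split` when the projected pieces land on more than
#' one target chromosome, mix strands, or leave internal gaps larger than
#' twice the query length; otherwise `unique`, with the target spanning the
#' first to last projected base.
#'
#' @param regions interval data.frame (query species coordinates).
#' @param map an `ortho_map` whose A side matches the query species.
#' @return data.table with one row per query: `status`
#'   (`unique`/`split`/`unmapped`) and target `chrom`, `start`, `end`
#'   (NA unless unique).
#' @export
project_intervals <- function(regions, map, ...) {
  r <- data.table::as.data.table(regions)
  validate_intervals(r)
  m <- data.table::as.data.table(map)
  if (nrow(r) && length(unique(r$species)) == 1 &&
      nrow(m) && r$species[1] != m$species_a[1]) {
    stop("query species does not match map A side")
  }
  qb <- data.table::data.table(species = m$species_a, chrom = m$chrom_a,
                               start = m$start_a, end = m$end_a)
  hits <- interval_overlaps(r, qb)
  out <- data.table::data.table(status = rep("unmapped", nrow(r)),
                                chrom = NA_character_,
                                start = NA_real_, end = NA_real_)
  if (nrow(hits) == 0) return(out)
  # mapped sub-spans, affine within each block
  qs <- pmax(r$start[hits$i], m$start_a[hits$j])
  qe <- pmin(r$end[hits$i], m$end_a[hits$j])
  plus <- m$strand_b[hits$j] == "+"
  ts <- ifelse(plus, m$start_b[hits$j] + (qs - m$start_a[hits$j]),
               m$end_b[hits$j] - (qe - m$start_a[hits$j]))
  te <- ts + (qe - qs)
  nhit <- tabulate(hits$i, nbins = nrow(r))
  single <- nhit[hits$i] == 1L
  if (any(single)) {
    si <- hits$i[single]
    out$status[si] <- "unique"
    out$chrom[si] <- m$chrom_b[hits$j[single]]
    out$start[si] <- ts[single]
    out$end[si] <- te[single]
  }
  if (any(!single)) {
    pieces <- data.table::data.table(i = hits$i[!single],
                                     tchrom = m$chrom_b[hits$j[!single]],
                                     tstrand = m$strand_b[hits$j[!single]],
                                     ts = ts[!single], te = te[!single])
    agg <- pieces[, list(nchrom = data.table::uniqueN(tchrom),
                         nstrand = data.table::uniqueN(tstrand),
                         tchrom = tchrom[1],
                         lo = min(ts), hi = max(te),
                         covered = sum(te - ts)), by = i]
    qlen <- r$end[agg$i] - r$start[agg$i]
    gap <- (agg$hi - agg$lo) - agg$covered
    split <- agg$nchrom > 1 | agg$nstrand > 1 | gap > 2 * qlen
    out$status[agg$i] <- ifelse(split, "split", "unique")
    uni <- agg$i[!split]
    out$chrom[uni] <- agg$tchrom[!split]
    out$start[uni] <- agg$lo[!split]
    out$end[uni] <- agg$hi[!split]
  }
  out[]
}

#' @rdname project_intervals
#' @param region a single-row interval.
#' @export
project <- function(region, map, ...) {
  res <- project_intervals(data.table::as.data.table(region)[1], map)
  list(status = res$status,
       target = if (res$status == "unique") {
         list(chrom = res$chrom, start = res$start, end = res$end)
       } else NULL)
}

#' Conservation call for a projected element
#'
#' `unalignable` when the projection is not unique; `conserved` when the
#' projected interval overlaps any marked region in the target species by at
#' least `min_overlap` of the projected interval's length; `absent`
#' otherwise.
#'
#' @param projection one row of [project_intervals()] output.
#' @param target_elements marked regions (consensus peaks) of the relevant
#'   mark in the target species.
#' @param target_species species id of the target side.
#' @param min_overlap required fraction of the projected interval.
#' @return one of `"conserved"`, `"absent"`, `"unalignable"`.
#' @export
call_conservation <- function(projection, target_elements, target_species,
                              min_overlap = 0.5) {
  conservation_calls(projection, target_elements, target_species, min_overlap)
}

#' @rdname call_conservation
#' @param projections multi-row [project_intervals()] output.
#' @export
conservation_calls <- function(projections, target_elements, target_species,
                               min_overlap = 0.5) {
  pr <- data.table::as.data.table(projections)
  res <- rep("unalignable", nrow(pr))
  uni <- which(pr$status == "unique")
  if (length(uni)) {
    q <- data.table::data.table(species = target_species, chrom = pr$chrom[uni],
                                start = pr$start[uni], end = pr$end[uni])
    tg <- data.table::as.data.table(target_elements)
    ov <- interval_overlaps(q, tg)
    hit <- unique(ov$i[ov$frac_a >= min_overlap])
    res[uni] <- "absent"
    res[uni[hit]] <- "conserved"
  }
  res
}

#' Per-mark enrichment state at orthologous locations
#'
#' For each projected query, whether the target location carries H3K4me3
#' and/or H3K27ac consensus enrichment (at `min_overlap` of the projected
#' interval). Used for majority-rule classification of conserved elements.
#'
#' @inheritParams conservation_calls
#' @param k4_targets,k27_targets per-mark consensus peak tables of the target
#'   species.
#' @return data.table with logical `k4`, `k27` and character `state`
#'   (`dual`/`k4_only`/`k27_only`/`none`/`unalignable`).
#' @export
mark_state_at <- function(projections, k4_targets, k27_targets, target_species,
                          min_overlap = 0.5) {
  c4 <- conservation_calls(projections, k4_targets, target_species, min_overlap)
  c27 <- conservation_calls(projections, k27_targets, target_species, min_overlap)
  k4 <- c4 == "conserved"
  k27 <- c27 == "conserved"
  state <- ifelse(c4 == "unalignable", "unalignable",
           ifelse(k4 & k27, "dual",
           ifelse(k4, "k4_only", ifelse(k27, "k27_only", "none"))))
  data.table::data.table(k4 = k4, k27 = k27, state = state)
}

# marks carried by an element class
marks_of_class <- function(cls) {
  list(promoter_dual = c(TRUE, TRUE), promoter_k4 = c(TRUE, FALSE),
       enhancer = c(FALSE, TRUE))[cls]
}

# element-level conservation: an element is conserved in the target species
# when at least one of its own marks is enriched at the orthologous location;
# single projection pass and one overlap join over both marks
element_conservation <- function(elements, map, k4_targets, k27_targets,
                                 target_species, min_overlap = 0.5) {
  el <- data.table::as.data.table(elements)
  pr <- project_intervals(el, map)
  n <- nrow(pr)
  k4 <- k27 <- rep(FALSE, n)
  uni <- which(pr$status == "unique")
  if (length(uni)) {
    q <- data.table::data.table(species = target_species, chrom = pr$chrom[uni],
                                start = pr$start[uni], end = pr$end[uni])
    t4 <- data.table::as.data.table(k4_targets)
    t27 <- data.table::as.data.table(k27_targets)
    comb <- data.table::data.table(
      species = target_species,
      chrom = c(t4$chrom, t27$chrom),
      start = c(t4$start, t27$start),
      end = c(t4$end, t27$end),
      is_k4 = rep(c(TRUE, FALSE), c(nrow(t4), nrow(t27))))
    ov <- interval_overlaps(q, comb)
    keep_rows <- which(ov$frac_a >= min_overlap)
    ov <- ov[keep_rows]
    k4[uni[unique(ov$i[comb$is_k4[ov$j]])]] <- TRUE
    k27[uni[unique(ov$i[!comb$is_k4[ov$j]])]] <- TRUE
  }
  mk <- do.call(rbind, marks_of_class(el$class))
  conserved <- (mk[, 1] & k4) | (mk[, 2] & k27)
  status <- ifelse(pr$status != "unique", "unalignable",
                   ifelse(conserved, "conserved", "absent"))
  state <- ifelse(pr$status != "unique", "unalignable",
           ifelse(k4 & k27, "dual",
           ifelse(k4, "k4_only", ifelse(k27, "k27_only", "none"))))
  data.table::data.table(status = status, state = state, k4 = k4, k27 = k27)
}

#' Reciprocal pairwise conservation ratio
#'
#' Fraction of species-A elements (of one class group) conserved in species
#' B among those uniquely alignable, averaged with the reciprocal B-in-A
#' fraction.
#'
#' @param elements_a,elements_b classified consensus elements of the chosen
#'   class in each species.
#' @param map_ab,map_ba orthology maps in each direction.
#' @param targets_a,targets_b lists with per-mark consensus tables `k4`,
#'   `k27` for each species.
#' @param min_overlap required overlap fraction.
#' @return list: `ratio` (averaged), `ratio_ab`, `ratio_ba`, `n_alignable_ab`,
#'   `n_alignable_ba`. Ratios are NA when no element is alignable.
#' @export
pairwise_conservation_ratio <- function(elements_a, elements_b, map_ab, map_ba,
                                        targets_a, targets_b, min_overlap = 0.5) {
  one_way <- function(el, map, tg, sp) {
    if (nrow(el) == 0) return(c(NA_real_, 0))
    cc <- element_conservation(el, map, tg$k4, tg$k27, sp, min_overlap)
    n_al <- sum(cc$status != "unalignable")
    if (n_al == 0) return(c(NA_real_, 0))
    c(sum(cc$status == "conserved") / n_al, n_al)
  }
  ab <- one_way(elements_a, map_ab, targets_b, map_ab$species_b[1])
  ba <- one_way(elements_b, map_ba, targets_a, map_ba$species_b[1])
  list(ratio = mean(c(ab[1], ba[1])), ratio_ab = ab[1], ratio_ba = ba[1],
       n_alignable_ab = ab[2], n_alignable_ba = ba[2])
}

#' Coverage-based false-negative fraction for absent calls
#'
#' Fraction of absent-site read coverages exceeding the upper tail of the
#' control coverage distribution (mean + 1.96 sd, sample sd).
#'
#' @param absent_site_coverages,control_coverages numeric vectors.
#' @return fraction in `[0, 1]`.
#' @export
coverage_false_negative_fraction <- function(absent_site_coverages,
                                             control_coverages) {
  stopifnot(length(absent_site_coverages) > 0, length(control_coverages) > 0)
  s <- stats::sd(control_coverages)
  if (is.na(s)) s <- 0   # single control value: threshold at the mean
  thr <- mean(control_coverages) + 1.96 * s
  mean(absent_site_coverages > thr)
}
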