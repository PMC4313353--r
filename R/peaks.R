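#' Reproducible consensus peaks from replicate peak calls
#'
#' A peak is reproducible when it overlaps peaks from at least
#' `min_replicates - 1` other biological replicates, with an overlap of at
#' least `min_overlap` of the shorter peak's length. Reproducible peaks
#' connected by qualifying overlaps (across all replicates, transitively) are
#' merged into one consensus region; non-reproducible peaks are discarded.
#' When only one replicate exists and `single_replicate_ok` is set, all peaks
#' are retained verbatim (the single-individual code path).
#'
#' @param peaks data.frame of replicate peaks for one species and one mark:
#'   columns `species`, `chrom`, `start`, `end`, `replicate`,
#'   `fold_enrichment` (and optionally `name`).
#' @param min_replicates minimum number of supporting replicates.
#' @param min_overlap required overlap fraction (of the shorter peak).
#' @param single_replicate_ok retain all peaks when only one replicate exists.
#' @return consensus data.table: `species`, `chrom`, `start`, `end`, `name`,
#'   `intensity` (mean fold enrichment over supporting peaks),
#'   `reproducibility` (supporting replicates / total replicates),
#'   `n_replicates`.
#' @export
build_consensus <- function(peaks, min_replicates = 2L, min_overlap = 0.5,
                            single_replicate_ok = FALSE) {
  stopifnot(min_overlap > 0, min_overlap <= 1)
  pk <- data.table::as.data.table(peaks)
  validate_intervals(pk)
  empty <- data.table::data.table(species = character(), chrom = character(),
                                  start = numeric(), end = numeric(),
                                  name = character(), intensity = numeric(),
                                  reproducibility = numeric(),
                                  n_replicates = integer())
  if (nrow(pk) == 0) return(empty)
  n_rep <- length(unique(pk$replicate))
  if (n_rep == 1 && single_replicate_ok) {
    out <- pk[, list(species, chrom, start, end)]
    out[, `:=`(name = sprintf("c%05d", .I), intensity = pk$fold_enrichment,
               reproducibility = 1, n_replicates = 1L)]
    data.table::setorder(out, chrom, start)
    out[, name := sprintf("c%05d", .I)]
    return(out[])
  }
  if (min_replicates > n_rep) {
    warning("min_replicates (", min_replicates, ") exceeds available replicates (",
            n_rep, "); no consensus peaks")
    return(empty)
  }
  ov <- interval_overlaps(pk, pk)
  ov <- ov[i < j & pk$replicate[i] != pk$replicate[j] &
             pmax(frac_a, frac_b) >= min_overlap]
  # reproducibility: distinct partner replicates per peak
  partner <- data.table::rbindlist(list(
    data.table::data.table(p = ov$i, r = pk$replicate[ov$j]),
    data.table::data.table(p = ov$j, r = pk$replicate[ov$i])))
  n_other <- partner[, data.table::uniqueN(r), by = p]
  good <- rep(FALSE, nrow(pk))
  good[n_other$p[n_other$V1 >= min_replicates - 1L]] <- TRUE
  if (!any(good)) return(empty)
  ov <- ov[good[i] & good[j]]
  memb <- overlap_components(nrow(pk), ov$i, ov$j)
  gi <- which(good)
  grp <- memb[gi]
  out <- data.table::data.table(
    species = pk$species[gi], chrom = pk$chrom[gi],
    start = pk$start[gi], end = pk$end[gi],
    fold = pk$fold_enrichment[gi], rep = pk$replicate[gi], grp = grp)
  out <- out[, list(species = species[1], chrom = chrom[1],
                    start = min(start), end = max(end),
                    intensity = mean(fold),
                    reproducibility = data.table::uniqueN(rep) / n_rep,
                    n_replicates = data.table::uniqueN(rep)),
             by = grp]
  data.table::setorder(out, chrom, start)
  out[, name := sprintf("c%05d", .I)]
  out[, grp := NULL]
  data.table::setcolorder(out, c("species", "chrom", "start", "end", "name",
                                 "intensity", "reproducibility", "n_replicates"))
  out[]
}

# connected components over an overlap-edge list; vertices without edges are
# singletons
overlap_components <- function(n, i, j) {
  if (!length(i)) return(seq_len(n))
  g <- igraph::make_graph(rbind(i, j), n = n, directed = FALSE)
  igraph::components(g)$membership
}

#' Classify consensus peaks into promoter/enhancer mark classes
#'
#' H3K4me3 and H3K27ac consensus peaks overlapping by at least `min_overlap`
#' of the shorter peak are merged (transitively) into dual-marked
#' `promoter_dual` elements; remaining H3K4me3 peaks become `promoter_k4`
#' and remaining H3K27ac peaks become `enhancer`. The three classes
#' partition all input consensus peaks.
#'
#' @param k4_consensus,k27_consensus outputs of [build_consensus()] for the
#'   two marks.
#' @param min_overlap required overlap fraction (of the shorter peak).
#' @return data.table of consensus elements with columns `species`, `chrom`,
#'   `start`, `end`, `name`, `class`, `intensity`, `reproducibility`,
#'   `k4_start`, `k4_end`, `k27_start`, `k27_end` (per-mark sub-spans, NA
#'   where the mark is absent).
#' @export
classify_elements <- function(k4_consensus, k27_consensus, min_overlap = 0.5) {
  k4 <- data.table::as.data.table(k4_consensus)
  k27 <- data.table::as.data.table(k27_consensus)
  ov <- interval_overlaps(k4, k27)
  ov <- ov[pmax(frac_a, frac_b) >= min_overlap]
  n4 <- nrow(k4); n27 <- nrow(k27)
  memb <- overlap_components(n4 + n27, ov$i, ov$j + n4)
  out <- list()
  if (nrow(ov)) {
    inv4 <- sort(unique(ov$i)); inv27 <- sort(unique(ov$j))
    comb <- rbind(
      data.table::data.table(grp = memb[inv4], species = k4$species[inv4],
                             chrom = k4$chrom[inv4], start = k4$start[inv4],
                             end = k4$end[inv4], intensity = k4$intensity[inv4],
                             reproducibility = k4$reproducibility[inv4],
                             mark = "k4"),
      data.table::data.table(grp = memb[n4 + inv27], species = k27$species[inv27],
                             chrom = k27$chrom[inv27], start = k27$start[inv27],
                             end = k27$end[inv27], intensity = k27$intensity[inv27],
                             reproducibility = k27$reproducibility[inv27],
                             mark = "k27"))
    out[[1]] <- comb[, list(
      species = species[1], chrom = chrom[1],
      start = min(start), end = max(end), class = "promoter_dual",
      intensity = mean(intensity), reproducibility = mean(reproducibility),
      k4_start = min(start[mark == "k4"]), k4_end = max(end[mark == "k4"]),
      k27_start = min(start[mark == "k27"]), k27_end = max(end[mark == "k27"])),
      by = grp][, grp := NULL]
  }
  solo4 <- setdiff(seq_len(n4), if (nrow(ov)) ov$i else integer())
  if (length(solo4)) {
    out[[length(out) + 1]] <- data.table::data.table(
      species = k4$species[solo4], chrom = k4$chrom[solo4],
      start = k4$start[solo4], end = k4$end[solo4], class = "promoter_k4",
      intensity = k4$intensity[solo4], reproducibility = k4$reproducibility[solo4],
      k4_start = k4$start[solo4], k4_end = k4$end[solo4],
      k27_start = NA_real_, k27_end = NA_real_)
  }
  solo27 <- setdiff(seq_len(n27), if (nrow(ov)) ov$j else integer())
  if (length(solo27)) {
    out[[length(out) + 1]] <- data.table::data.table(
      species = k27$species[solo27], chrom = k27$chrom[solo27],
      start = k27$start[solo27], end = k27$end[solo27], class = "enhancer",
      intensity = k27$intensity[solo27], reproducibility = k27$reproducibility[solo27],
      k4_start = NA_real_, k4_end = NA_real_,
      k27_start = k27$start[solo27], k27_end = k27$end[solo27])
  }
  res <- data.table::rbindlist(out)
  if (nrow(res) == 0) return(res)
  data.table::setorder(res, chrom, start)
  res[, name := sprintf("el%05d", .I)]
  data.table::setcolorder(res, c("species", "chrom", "start", "end", "name", "class"))
  res[]
}

#' Mean fold enrichment over supporting replicate peaks
#'
#' @param folds positive fold-enrichment values of the supporting peaks.
#' @return arithmetic mean.
#' @export
element_intensity <- function(folds) {
  if (!length(folds)) stop("empty support")
  mean(folds)
}

#' Replicate peaks of one species and mark from a synthetic world
#'
#' @param world a `synth_world`.
#' @param species species id.
#' @param mark `"H3K4me3"` or `"H3K27ac"`.
#' @return replicate peak data.table.
#' @export
world_peaks <- function(world, species, mark) {
  sel <- world$peaks$species == species & world$peaks$mark == mark
  world$peaks[which(sel)]
}

#' Consensus elements for every species of a world
#'
#' Runs [build_consensus()] per mark and [classify_elements()] for each
#' species; species listed in the config's `single_replicate_species` retain
#' all peaks.
#'
#' @param world a `synth_world`.
#' @param min_replicates,min_overlap see [build_consensus()].
#' @return named list per species: `k4`, `k27` (consensus tables) and
#'   `elements` (classified).
#' @export
consensus_all <- function(world, min_replicates = 2L, min_overlap = 0.5) {
  res <- lapply(world$species, function(sp) {
    single <- sp %in% world$config$single_replicate_species
    k4 <- build_consensus(world_peaks(world, sp, "H3K4me3"),
                          min_replicates, min_overlap, single_replicate_ok = single)
    k27 <- build_consensus(world_peaks(world, sp, "H3K27ac"),
                           min_replicates, min_overlap, single_replicate_ok = single)
    list(k4 = k4, k27 = k27, elements = classify_elements(k4, k27, min_overlap))
  })
  names(res) <- world$species
  res
}
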