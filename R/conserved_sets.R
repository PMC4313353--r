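#' Species panels and clade definitions
#'
#' A panel fixes the anchor species, the required high-quality species set
#' for highly-conserved calls, and named clades (full topological membership
#' plus the designated high-quality species required within each clade, and
#' a reference species per clade).
#'
#' @param anchor anchor species id.
#' @param required species that must all show enrichment for an element to
#'   be called highly conserved (the high-quality genome panel; excludes the
#'   anchor itself).
#' @param clades named list; each entry a list with `members` (all species in
#'   the clade), `required` (designated high-quality members) and `reference`.
#' @return a `species_panel` list.
#' @export
species_panel <- function(anchor, required, clades = list()) {
  stopifnot(!anchor %in% required)
  for (cl in clades) {
    stopifnot(all(cl$required %in% cl$members), cl$reference %in% cl$members)
  }
  structure(list(anchor = anchor, required = required, clades = clades),
            class = "species_panel")
}

#' Default panel for the bundled 20-taxon mammal fixture
#'
#' Nine non-anchor high-quality placental genomes (with the anchor, the
#' ten-species panel) and four study clades with their reference species.
#'
#' @return a `species_panel`.
#' @export
default_panel <- function() {
  species_panel(
    anchor = "human",
    required = c("macaque", "marmoset", "mouse", "rat", "rabbit",
                 "cow", "pig", "dog", "cat"),
    clades = list(
      primates = list(members = c("human", "macaque", "vervet", "marmoset"),
                      required = c("human", "macaque", "marmoset"),
                      reference = "human"),
      rodents = list(members = c("mouse", "rat", "guinea_pig", "naked_mole_rat",
                                 "rabbit"),
                     required = c("mouse", "rat", "rabbit"),
                     reference = "mouse"),
      ungulates = list(members = c("cow", "sheep", "dolphin", "sei_whale", "pig"),
                       required = c("cow", "pig"),
                       reference = "cow"),
      carnivores = list(members = c("dog", "ferret", "cat"),
                        required = c("dog", "cat"),
                        reference = "dog")))
}

# anchor's own displayed state, derived from its element class
own_state <- function(cls) {
  c(promoter_dual = "dual", promoter_k4 = "k4_only", enhancer = "k27_only")[cls]
}

#' Identify highly conserved elements
#'
#' An anchor element is highly conserved when its orthologous location shows
#' enrichment for at least one histone mark in every required-panel species
#' (additional supporting species are recorded but not required). Elements
#' are classed promoter/enhancer by majority rule over the observed mark
#' states across all species (anchor included).
#'
#' @param anchor_elements classified consensus elements of the anchor.
#' @param states element-by-species mark-state matrix from
#'   [conservation_profile()].
#' @param panel a [species_panel()].
#' @return data.table of retained elements with `assigned_class`,
#'   `n_support` (species with any enrichment, anchor excluded) and
#'   `all_k4_only` flag.
#' @export
find_highly_conserved <- function(anchor_elements, states, panel) {
  el <- data.table::as.data.table(anchor_elements)
  req <- panel$required
  stopifnot(all(req %in% colnames(states)))
  enriched <- states[, req, drop = FALSE] %in% c("dual", "k4_only", "k27_only")
  enriched <- matrix(enriched, nrow = nrow(states))
  keep <- rowSums(enriched) == length(req)
  out <- el[keep]
  if (nrow(out) == 0) {
    out[, `:=`(assigned_class = character(), n_support = integer(),
               all_k4_only = logical())]
    return(out[])
  }
  st_keep <- states[keep, , drop = FALSE]
  full <- cbind(st_keep, anchor = unname(own_state(el$class[keep])))
  cls <- apply(full, 1, classify_majority)
  nz <- c("dual", "k4_only", "k27_only")
  out[, assigned_class := cls]
  out[, n_support := rowSums(matrix(st_keep %in% nz, nrow = nrow(st_keep)))]
  out[, all_k4_only := apply(full, 1, function(v) {
    v <- v[v %in% nz]; length(v) > 0 && all(v == "k4_only")
  })]
  out[]
}

#' Majority-rule promoter/enhancer classification
#'
#' Promoter states (`dual`, `k4_only`) are tallied against enhancer states
#' (`k27_only`); ties break to promoter since dual marking subsumes H3K27ac.
#'
#' @param state_vector character states per species
#'   (`dual`/`k4_only`/`k27_only`/`none`/`unalignable`).
#' @return `"promoter"` or `"enhancer"`.
#' @export
classify_majority <- function(state_vector) {
  pv <- sum(state_vector %in% c("dual", "k4_only"))
  ev <- sum(state_vector == "k27_only")
  if (pv + ev == 0) stop("no enriched state: cannot classify")
  if (pv >= ev) "promoter" else "enhancer"
}

#' Permutation null for the count of panel-wide conserved elements
#'
#' Each iteration independently permutes, per species and per histone mark,
#' which anchor elements carry that stratum's conserved labels (preserving
#' the per-stratum conserved counts) and counts elements conserved (either
#' mark) in every panel species. Under this relabelling the per-species
#' conserved sets are independent uniform random subsets of the anchor
#' elements, so the null count is the intersection size of independent random
#' subsets; the default `"hypergeometric"` method samples that intersection
#' exactly by iterated hypergeometric draws, while `"permute"` shuffles
#' labels literally. The two are distributionally identical; the sampler is
#' used for large iteration counts.
#'
#' @param observed_count observed number of panel-wide conserved elements.
#' @param per_species_conserved_sets named list (one entry per panel
#'   species), each a list of per-mark vectors of conserved element ids.
#' @param universe vector of all anchor element ids.
#' @param n_iter number of permutations.
#' @param seed integer seed.
#' @param method `"hypergeometric"` (exact-equivalent sampler) or
#'   `"permute"` (literal relabelling).
#' @return list: `observed`, `p` (add-one estimator), `p_label` (`"< 1/n"`
#'   form when no null draw reaches the observed count), `null_mean`,
#'   `null_sd`, `n_iter`.
#' @export
permutation_test_conserved_count <- function(observed_count,
                                             per_species_conserved_sets,
                                             universe,
                                             n_iter = 10000L,
                                             seed = 1L,
                                             method = c("hypergeometric", "permute")) {
  method <- match.arg(method)
  stopifnot(n_iter >= 1)
  set.seed(seed)
  n <- length(universe)
  stopifnot(n > 0)
  counts <- lapply(per_species_conserved_sets, function(marks) {
    vapply(marks, length, integer(1))
  })
  if (method == "hypergeometric") {
    x <- rep(n, n_iter)  # start from the full universe, intersect per species
    for (ct in counts) {
      u <- ct[1]
      if (length(ct) > 1) for (k in ct[-1]) {
        ovl <- stats::rhyper(n_iter, u, n - u, k)
        u <- u + k - ovl
      }
      x <- stats::rhyper(n_iter, x, n - x, u)
    }
    null_counts <- x
  } else {
    null_counts <- vapply(seq_len(n_iter), function(it) {
      sets <- lapply(counts, function(ct) {
        ids <- unlist(lapply(ct, function(k) sample(universe, k)))
        unique(ids)
      })
      length(Reduce(intersect, sets))
    }, integer(1))
  }
  exceed <- sum(null_counts >= observed_count)
  p <- (1 + exceed) / (1 + n_iter)
  list(observed = observed_count, p = p,
       p_label = if (exceed == 0) paste0("< ", format(1 / n_iter)) else format(p),
       null_mean = mean(null_counts), null_sd = stats::sd(null_counts),
       n_iter = n_iter, method = method)
}

# note: in the hypergeometric path the per-species union of mark subsets is
# itself sampled (overlap of two random subsets is hypergeometric), then the
# running intersection across species is thinned hypergeometrically.

#' Identify lineage-specific elements
#'
#' Elements of a clade's reference species conserved in all designated
#' within-clade species and not conserved in any species outside the clade
#' (non-designated clade members are neither required nor disqualifying;
#' unalignable species are non-informative). Classified by majority rule
#' over within-clade states.
#'
#' @param ref_elements classified consensus elements of the clade reference.
#' @param calls,states matrices from [conservation_profile()] anchored at the
#'   reference species.
#' @param clade list with `members`, `required`, `reference`.
#' @return data.table of retained elements with `assigned_class`.
#' @export
find_lineage_specific <- function(ref_elements, calls, states, clade) {
  el <- data.table::as.data.table(ref_elements)
  req <- setdiff(clade$required, clade$reference)
  outside <- setdiff(colnames(calls), clade$members)
  ok_in <- rowSums(calls[, req, drop = FALSE] == "conserved") == length(req)
  ok_out <- rowSums(calls[, outside, drop = FALSE] == "conserved") == 0
  keep <- ok_in & ok_out
  out <- el[keep]
  if (nrow(out) == 0) {
    out[, assigned_class := character()]
    return(out[])
  }
  in_clade <- intersect(colnames(states), setdiff(clade$members, clade$reference))
  full <- cbind(states[keep, in_clade, drop = FALSE],
                reference = unname(own_state(el$class[keep])))
  out[, assigned_class := apply(full, 1, classify_majority)]
  out[]
}

#' Identify recently evolved elements
#'
#' Reference-species elements with no conserved call in any compared species;
#' species where the projection is not unique are non-informative (they
#' neither rescue nor disqualify). Promoter/enhancer classification is the
#' reference species' own mark class.
#'
#' @param ref_elements classified consensus elements of the reference.
#' @param calls call matrix from [conservation_profile()].
#' @return data.table of retained elements with `assigned_class`.
#' @export
find_recently_evolved <- function(ref_elements, calls) {
  el <- data.table::as.data.table(ref_elements)
  keep <- rowSums(calls == "conserved") == 0
  out <- el[keep]
  out[, assigned_class := ifelse(class == "enhancer", "enhancer", "promoter")]
  out[]
}
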