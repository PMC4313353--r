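#' Anchor-centric conservation profiles
#'
#' For each element of an anchor species, counts the number of other species
#' where its DNA uniquely projects (`n_alignable`) and where its activity is
#' conserved (`n_conserved`), together with the per-species call and mark
#' state. These are the 2-D alignability-by-conservation summaries that
#' contrast stable promoters with fast-turning-over enhancers.
#'
#' @param anchor_elements classified consensus elements of the anchor species.
#' @param maps named list of `ortho_map`s, anchor as A side, one per target
#'   species.
#' @param targets named list (same names) of per-mark consensus tables, each
#'   a list with components `k4` and `k27`.
#' @param min_overlap required overlap fraction for conservation calls.
#' @return list with `profile` (data.table: `id`, `class`, `n_alignable`,
#'   `n_conserved`, `ratio`), `calls` and `states` (element x species
#'   character matrices).
#' @export
conservation_profile <- function(anchor_elements, maps, targets, min_overlap = 0.5) {
  el <- data.table::as.data.table(anchor_elements)
  sps <- names(maps)
  calls <- matrix(NA_character_, nrow(el), length(sps),
                  dimnames = list(el$name, sps))
  states <- calls
  for (s in sps) {
    cc <- element_conservation(el, maps[[s]], targets[[s]]$k4, targets[[s]]$k27,
                               s, min_overlap)
    calls[, s] <- cc$status
    states[, s] <- cc$state
  }
  n_al <- rowSums(calls != "unalignable")
  n_co <- rowSums(calls == "conserved")
  prof <- data.table::data.table(id = el$name, class = el$class,
                                 n_alignable = n_al, n_conserved = n_co,
                                 ratio = ifelse(n_al > 0, n_co / n_al, NA_real_))
  list(profile = prof, calls = calls, states = states)
}

#' Conservation ratio of a profile
#'
#' Number of species with conserved activity divided by the number of
#' uniquely mapped (alignable) species; undefined (NA) when nothing aligns.
#'
#' @param n_conserved,n_alignable integer vectors.
#' @return numeric vector of ratios.
#' @export
conservation_ratio <- function(n_conserved, n_alignable) {
  ifelse(n_alignable >= 1, n_conserved / n_alignable, NA_real_)
}

#' Exponential-decay fit of conservation against divergence time
#'
#' Fits `ratio = A * exp(-t / tau)` by ordinary least squares on the log
#' scale (`log(ratio) = log(A) - t/tau`), the model under which pairwise
#' conservation decays linearly on a log axis. The amplitude is left free by
#' default, absorbing divergence-independent technical non-conservation; the
#' half-life is reported from the slope alone, with a 95% CI from the
#' t-interval of the slope (monotone transform of its endpoints).
#'
#' @param points data.frame with columns `t` (divergence, Ma) and `ratio`
#'   in (0, 1]; non-positive ratios are dropped with a warning.
#' @param amplitude_free if `FALSE`, constrains A = 1 (regression through
#'   the origin on the log scale).
#' @return object of class `decay_fit`: `tau` (mean lifetime, Ma),
#'   `half_life` (Ma), `amplitude`, `ci95_half_life`, `r_squared`, `n`.
#' @export
fit_exponential_decay <- function(points, amplitude_free = TRUE) {
  p <- data.table::as.data.table(points)
  stopifnot(all(c("t", "ratio") %in% names(p)))
  bad <- !is.finite(p$ratio) | p$ratio <= 0 | !is.finite(p$t)
  if (any(bad)) {
    warning(sum(bad), " non-positive or missing ratio point(s) dropped")
    p <- p[!bad]
  }
  if (nrow(p) < 3) stop("need at least 3 usable points")
  if (all(p$t == 0)) stop("all points at divergence 0")
  y <- log(p$ratio)
  fit <- if (amplitude_free) stats::lm(y ~ t, data = p) else stats::lm(y ~ t + 0, data = p)
  sl_name <- "t"
  slope <- stats::coef(fit)[[sl_name]]
  ci <- stats::confint(fit, sl_name, level = 0.95)
  hl_from_slope <- function(b) if (b < 0) -log(2) / b else Inf
  half_life <- hl_from_slope(slope)
  # slope CI lower (more negative) -> shorter half-life bound
  ci_hl <- c(hl_from_slope(ci[1]), hl_from_slope(ci[2]))
  structure(list(
    tau = half_life / log(2),
    half_life = half_life,
    amplitude = if (amplitude_free) exp(stats::coef(fit)[["(Intercept)"]]) else 1,
    ci95_half_life = ci_hl,
    r_squared = summary(fit)$r.squared,
    slope = slope,
    n = nrow(p)), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("exponential decay fit (n = %d): half-life %.0f Ma [%.0f-%.0f], mean lifetime %.0f Ma, R2 = %.3f\n",
              x$n, x$half_life, x$ci95_half_life[1], x$ci95_half_life[2],
              mean_lifetime(x$half_life), x$r_squared))
  invisible(x)
}

#' Mean lifetime from a half-life
#'
#' For exponential decay with time constant tau, half-life = tau * ln 2 and
#' the mean lifetime is tau = half-life / ln 2.
#'
#' @param half_life Ma, positive.
#' @return mean lifetime in Ma.
#' @export
mean_lifetime <- function(half_life) {
  stopifnot(all(half_life > 0))
  half_life / log(2)
}

#' Neighbor-joining tree from a conservation-distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via ape) on a symmetric distance
#' matrix, typically `1 - pairwise conservation ratio`; negative branch
#' lengths are clamped to zero.
#'
#' @param d symmetric numeric matrix with zero diagonal and species labels.
#' @return unrooted `ape::phylo`.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("need at least 3 species")
  stopifnot(isTRUE(all.equal(d, t(d), tolerance = 1e-8)), all(diag(d) == 0))
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Pairwise conservation-ratio matrix over all species of a world
#'
#' Computes, for every unordered species pair, the reciprocal-averaged
#' conservation ratio of the chosen element class group.
#'
#' @param world a `synth_world`.
#' @param cons output of [consensus_all()].
#' @param class_group `"promoter"` (dual + H3K4me3-only) or `"enhancer"`.
#' @param species subset of species to compare (default all).
#' @param min_overlap required overlap fraction.
#' @return symmetric matrix of ratios with 1 on the diagonal.
#' @export
conservation_ratio_matrix <- function(world, cons, class_group = c("enhancer", "promoter"),
                                      species = world$species, min_overlap = 0.5) {
  class_group <- match.arg(class_group)
  conservation_ratio_matrices(world, cons, species, min_overlap,
                              groups = class_group)[[class_group]]
}

#' @rdname conservation_ratio_matrix
#' @param groups class groups to compute in one pass over the pairwise
#'   projections.
#' @export
conservation_ratio_matrices <- function(world, cons, species = world$species,
                                        min_overlap = 0.5,
                                        groups = c("promoter", "enhancer")) {
  group_classes <- list(promoter = c("promoter_dual", "promoter_k4"),
                        enhancer = "enhancer")[groups]
  n <- length(species)
  mats <- lapply(groups, function(g) {
    m <- matrix(NA_real_, n, n, dimnames = list(species, species))
    diag(m) <- 1
    m
  })
  names(mats) <- groups
  one_way <- function(a, b) {
    el <- cons[[a]]$elements
    cc <- element_conservation(el, orthology_map(world, a, b),
                               cons[[b]]$k4, cons[[b]]$k27, b, min_overlap)
    vapply(group_classes, function(cls) {
      sel <- el$class %in% cls
      n_al <- sum(sel & cc$status != "unalignable")
      if (n_al == 0) NA_real_ else sum(sel & cc$status == "conserved") / n_al
    }, numeric(1))
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- species[i]; b <- species[j]
    r <- (one_way(a, b) + one_way(b, a)) / 2
    for (g in groups) mats[[g]][i, j] <- mats[[g]][j, i] <- r[[g]]
  }
  mats
}

#' Decay-fit input points from a ratio matrix
#'
#' One point per unordered species pair: MRCA age vs averaged reciprocal
#' conservation ratio.
#'
#' @param m ratio matrix from [conservation_ratio_matrix()].
#' @param tree dated `phylo` covering the matrix species.
#' @return data.table with `a`, `b`, `t`, `ratio`.
#' @export
decay_points <- function(m, tree) {
  sp <- rownames(m)
  dv <- divergence_matrix(tree)[sp, sp]
  idx <- which(upper.tri(m), arr.ind = TRUE)
  data.table::data.table(a = sp[idx[, 1]], b = sp[idx[, 2]],
                         t = dv[idx], ratio = m[idx])
}
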