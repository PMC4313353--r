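#' Dated species trees
#'
#' Trees are `ape::phylo` objects with branch lengths in millions of years
#' (Ma). The bundled 20-taxon mammalian fixture tree is ultrametric with a
#' root depth of 180 Ma. Divergence time between two species is the age of
#' their most recent common ancestor (the x-axis of pairwise-decay plots),
#' not the patristic path length.
#'
#' @param path newick file with branch lengths in Ma.
#' @return an `ape::phylo`.
#' @export
read_species_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr$edge.length)) stop("tree has no branch lengths")
  tr
}

#' The bundled 20-taxon dated mammal tree
#'
#' @return an `ape::phylo`, ultrametric, depth 180 Ma.
#' @export
mammal_tree <- function() {
  read_species_tree(system.file("extdata", "mammal_tree.nwk", package = "regevo"))
}

# node ages (Ma before present) for an ultrametric-enough tree; ages indexed
# by node number (tips first, then internals)
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  ages <- max(depth) - depth
  ages[ages < 1e-8] <- 0
  ages
}

#' Divergence time between two species
#'
#' Age (Ma) of the most recent common ancestor; 0 for a species with itself.
#'
#' @param tree dated `phylo`.
#' @param a,b species (tip) labels.
#' @return numeric Ma.
#' @export
divergence_time <- function(tree, a, b) {
  ia <- match(a, tree$tip.label)
  ib <- match(b, tree$tip.label)
  if (is.na(ia) || is.na(ib)) stop("unknown species id: ", paste(c(a, b)[is.na(c(ia, ib))], collapse = ", "))
  if (ia == ib) return(0)
  m <- ape::getMRCA(tree, c(ia, ib))
  node_ages(tree)[m]
}

#' All pairwise divergence times
#'
#' @param tree dated `phylo`.
#' @return symmetric matrix of MRCA ages (Ma) with species labels.
#' @export
divergence_matrix <- function(tree) {
  # cophenetic distance is twice the MRCA age on an ultrametric tree; use
  # MRCA ages directly so non-ultrametric inputs still give MRCA ages
  n <- length(tree$tip.label)
  ages <- node_ages(tree)
  m <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  mr <- ape::mrca(tree)
  m[] <- ages[mr]
  diag(m) <- 0
  m
}

# tips (labels) descending from each node, as a list indexed by node number
clade_tips <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  out <- vector("list", n_node)
  for (i in seq_len(n_tip)) out[[i]] <- tree$tip.label[i]
  # process internal nodes children-first (edges are in preorder from root)
  for (e in rev(seq_len(nrow(tree$edge)))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    out[[p]] <- c(out[[p]], out[[ch]])
  }
  lapply(out, unique)
}

# edge table: parent, child, length, child age, parent age
edge_table <- function(tree) {
  ages <- node_ages(tree)
  data.table::data.table(parent = tree$edge[, 1],
                         child = tree$edge[, 2],
                         length = tree$edge.length,
                         age_child = ages[tree$edge[, 2]],
                         age_parent = ages[tree$edge[, 1]])
}
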