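## Ortholog clade selection from a gene tree: root on the paralog outgroup,
## then take the largest clade containing the reference and no paralog
## exemplar. Tree handling is delegated to ape.

#' Read a Newick gene tree
#'
#' Internal node labels (e.g. bootstrap supports) are tolerated. Leaf labels
#' must be unique so they can be matched to sequence ids.
#'
#' @param file Path to a Newick file.
#' @param text Optional Newick text given directly.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(file = NULL, text = NULL) {
  tree <- if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(file)
  if (is.null(tree)) stop("could not parse Newick input", call. = FALSE)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup) > 0L)
    stop("duplicate leaf label(s): ", paste(dup, collapse = ", "), call. = FALSE)
  tree
}

## tip labels under an internal node (or the tip itself)
.tips_under <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  unlist(lapply(kids, .tips_under, tree = tree), use.names = FALSE)
}

## support of the branch subtending `node`, NA when absent/blank
.node_support <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (is.null(tree$node.label) || node <= ntip) return(NA_real_)
  lab <- tree$node.label[node - ntip]
  if (is.null(lab) || is.na(lab) || !nzchar(lab)) return(NA_real_)
  suppressWarnings(as.numeric(lab))
}

#' Select the ortholog clade around a reference leaf
#'
#' Returns the leaf set of the largest clade that contains `ref_leaf` and no
#' paralog exemplar. An unrooted tree is first rooted on the branch
#' subtending the paralog exemplars' most recent common ancestor (the
#' paralogs act as the outgroup). If `min_support` is given, the clade's
#' subtending branch support must be at least that value; otherwise the
#' largest qualifying nested clade is taken. Branches without a support
#' label cannot be disqualified by `min_support`.
#'
#' If no clade larger than the reference leaf itself qualifies, the
#' singleton set is returned with a warning.
#'
#' @param tree An `ape::phylo` gene tree.
#' @param ref_leaf Reference leaf label.
#' @param paralog_leaves Non-empty character vector of paralog exemplar
#'   labels.
#' @param min_support Optional minimal branch support (same scale as the
#'   tree's node labels, typically 0-100).
#' @return Character vector of selected leaf labels.
#' @export
select_ortholog_clade <- function(tree, ref_leaf, paralog_leaves,
                                  min_support = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!ref_leaf %in% tree$tip.label)
    stop("reference leaf '", ref_leaf, "' not in tree", call. = FALSE)
  paralog_leaves <- unique(paralog_leaves)
  if (length(paralog_leaves) == 0L)
    stop("paralog_leaves must be non-empty", call. = FALSE)
  if (ref_leaf %in% paralog_leaves)
    stop("reference leaf cannot be a paralog exemplar", call. = FALSE)
  missing_p <- setdiff(paralog_leaves, tree$tip.label)
  if (length(missing_p) > 0L)
    stop("paralog leaf label(s) not in tree: ",
         paste(missing_p, collapse = ", "), call. = FALSE)

  if (!ape::is.rooted(tree)) {
    tree <- .root_on_paralogs(tree, paralog_leaves)
  }

  ntip <- length(tree$tip.label)
  ref_tip <- match(ref_leaf, tree$tip.label)
  ## walk from the reference tip rootwards; clades containing the reference
  ## are nested, so the largest paralog-free (and supported) one is the last
  ## qualifying ancestor on that path
  parent_of <- function(node) {
    p <- tree$edge[tree$edge[, 2L] == node, 1L]
    if (length(p) == 0L) NA_integer_ else p
  }
  best <- tree$tip.label[ref_tip]
  node <- ref_tip
  repeat {
    node <- parent_of(node)
    if (is.na(node)) break
    tips <- .tips_under(tree, node)
    if (any(paralog_leaves %in% tips)) break
    if (!is.null(min_support)) {
      sup <- .node_support(tree, node)
      if (!is.na(sup) && sup < min_support) next  # unsupported: keep walking
    }
    best <- tips
  }
  if (length(best) == 1L)
    warning("only the reference leaf itself is separable from the paralogs",
            call. = FALSE)
  best
}

.root_on_paralogs <- function(tree, paralog_leaves) {
  if (length(paralog_leaves) == 1L ||
      all(tree$tip.label %in% paralog_leaves)) {
    return(ape::root(tree, outgroup = paralog_leaves[1L], resolve.root = TRUE))
  }
  mrca <- ape::getMRCA(tree, paralog_leaves)
  ntip <- length(tree$tip.label)
  root_node <- ntip + 1L
  if (is.null(mrca) || mrca == root_node) {
    ## paralogs straddle the current (arbitrary) root: root on one exemplar
    return(ape::root(tree, outgroup = paralog_leaves[1L], resolve.root = TRUE))
  }
  ape::root(tree, node = mrca, resolve.root = TRUE)
}

#' Drop sequences whose species also possesses the paralog
#'
#' Lineages that retain the paralog may have partitioned the ancestral
#' functions between the two copies, so their ortholog is a weaker witness
#' of single-copy constraint; this filter keeps only sequences from species
#' without the paralog.
#'
#' @param ids Character vector of sequence ids.
#' @param species_of Named character vector or list mapping id to species.
#' @param paralog_species Character vector of species that possess the
#'   paralog.
#' @return List with `kept`, `removed` (both id vectors).
#' @export
exclude_species_with_paralog <- function(ids, species_of, paralog_species) {
  sp <- unlist(species_of)[ids]
  if (any(is.na(sp)))
    stop("no species mapping for id(s): ",
         paste(ids[is.na(sp)], collapse = ", "), call. = FALSE)
  bad <- sp %in% paralog_species
  list(kept = ids[!bad], removed = ids[bad])
}

#' Read an id-to-species table
#'
#' @param file TSV with columns `id` and `species`.
#' @return Named character vector mapping id to species.
#' @export
read_species_map <- function(file) {
  d <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("id", "species") %in% names(d)))
    stop("species map must have columns id, species", call. = FALSE)
  stats::setNames(d$species, d$id)
}
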