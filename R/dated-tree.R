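# Dated trees are ape "phylo" objects; node ages (Ma) are derived from branch
# lengths, taking the deepest tip as the present unless tips end above 0 Ma
# (fossil tips). Ages are attached on demand, never stored in the files.

#' Node ages of a dated tree
#'
#' Computes ages (Ma before present) for every tip and internal node from the
#' branch lengths, with the deepest root-to-tip path defining the present.
#' Tips within `extant_tol` of age 0 are snapped to exactly 0 (extant); tips
#' ending earlier are fossil tips.
#'
#' @param tree a binary `phylo` with branch lengths in Myr.
#' @param extant_tol tolerance (Myr) below which a tip age is treated as 0.
#' @return list with `ages` (numeric, indexed like ape nodes), `root_age`,
#'   and `is_fossil` (logical per tip).
#' @export
tree_ages <- function(tree, extant_tol = 0.001) {
  .validate_tree(tree)
  depth <- ape::node.depth.edgelength(tree)
  root_age <- max(depth[seq_len(ape::Ntip(tree))])
  ages <- root_age - depth
  ntip <- ape::Ntip(tree)
  snap <- seq_len(ntip)[ages[seq_len(ntip)] < extant_tol]
  ages[snap] <- 0
  list(ages = ages, root_age = root_age,
       is_fossil = ages[seq_len(ntip)] > 0)
}

.validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) abort("tree must be a 'phylo' object")
  if (is.null(tree$edge.length)) abort("tree must have branch lengths")
  if (any(tree$edge.length < 0)) abort("negative branch lengths in tree")
  tab <- tabulate(tree$edge[, 1])
  poly <- which(tab > 2)
  if (length(poly) > 0)
    abort(paste0("tree has polytomies at node(s): ",
                 paste(poly, collapse = ", "),
                 "; resolve them (e.g. ape::multi2di) before input"))
  invisible(tree)
}

# branches as a table: parent node, child node, child age, parent age
.branch_table <- function(tree, ages) {
  tibble(
    parent = tree$edge[, 1],
    child = tree$edge[, 2],
    age_child = ages[tree$edge[, 2]],
    age_parent = ages[tree$edge[, 1]])
}
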