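#' Read a rooted phylogeny from Newick text or file
#'
#' Thin validating wrapper around [ape::read.tree()]. The returned tree is an
#' ape `phylo` object and is guaranteed to satisfy the package's tree
#' contract: unique, non-empty tip labels; a branch length on every edge
#' (a missing root edge length is treated as 0); all lengths non-negative
#' and finite. Internal node labels and Newick comments are ignored;
#' surrounding quotes on tip labels are stripped.
#'
#' @param text Newick string (one tree, terminated by `;`). Exactly one of
#'   `text` and `file` must be given.
#' @param file path to a Newick file containing a single tree.
#' @return a `phylo` object with branch lengths in Myr.
#' @examples
#' tr <- read_newick("((A:1,B:1):2,C:3);")
#' total_branch_length(tr) # 7
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of 'text' or 'file'")
  if (!is.null(file)) {
    if (!file.exists(file)) stop("tree file not found: ", file)
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("malformed Newick: ",
                                          conditionMessage(e), call. = FALSE))
  if (is.null(tr)) stop("malformed Newick: no tree could be parsed")
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) stop("expected a single tree, found ", length(tr))
    tr <- tr[[1L]]
  }
  # strip surrounding quotes ape may keep on quoted labels
  tr$tip.label <- gsub("^'(.*)'$", "\\1", tr$tip.label)
  validate_tree(tr)
  tr
}

#' Write a phylogeny as Newick
#'
#' @param tree a `phylo` object.
#' @param file optional path; if `NULL` the Newick string is returned.
#' @return the Newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, file = NULL) {
  validate_tree(tree)
  txt <- ape::write.tree(tree)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Validate the package's tree contract
#'
#' Checks that `tree` is a rooted `phylo` with unique non-empty tip labels
#' and non-negative, finite branch lengths on every edge. Called by every
#' user-facing function that consumes a tree; exported for direct use.
#'
#' @param tree a `phylo` object.
#' @return `tree`, invisibly.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  tl <- tree$tip.label
  if (length(tl) < 1L) stop("tree has no tips")
  if (anyNA(tl) || any(!nzchar(tl))) stop("empty or missing tip labels")
  if (anyDuplicated(tl)) {
    dup <- unique(tl[duplicated(tl)])
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  }
  el <- tree$edge.length
  if (is.null(el) || length(el) != nrow(tree$edge))
    stop("branch lengths missing on one or more edges")
  if (any(!is.finite(el))) stop("non-finite or missing branch length")
  if (any(el < 0)) stop("negative branch length: ", min(el))
  re <- tree$root.edge
  if (!is.null(re) && (!is.finite(re) || re < 0))
    stop("invalid root edge length: ", re)
  # every tree is treated as rooted at its basal node; a basal polytomy
  # (e.g. a star tree) is a legitimate rooted shape here
  nparent <- tabulate(tree$edge[, 2L], nbins = max(tree$edge))
  root <- length(tl) + 1L
  if (length(tl) > 1L &&
      (nparent[root] != 0L || any(nparent[-root] != 1L)))
    stop("tree must have exactly one root and a unique parent per node")
  invisible(tree)
}

root_edge_len <- function(tree) if (is.null(tree$root.edge)) 0 else tree$root.edge

#' Total branch length of a tree
#'
#' Sum of all edge lengths, including the root edge if present. This is the
#' quantity that the evolutionary-distinctiveness metrics apportion among
#' the tips.
#'
#' @param tree a `phylo` object.
#' @return total branch length (Myr).
#' @export
total_branch_length <- function(tree) {
  validate_tree(tree)
  sum(tree$edge.length) + root_edge_len(tree)
}

#' Prune a tree to a set of tips
#'
#' Restricts the tree to `keep`, suppressing internal nodes left with a
#' single child by summing their edge lengths. The path from the surviving
#' subtree back to the original root is retained (as the root edge), so the
#' pruned tree keeps the full depth of every surviving tip; patristic
#' distances among kept tips are unchanged.
#'
#' @param tree a `phylo` object.
#' @param keep character vector of tip labels to retain (non-empty subset
#'   of `tree$tip.label`).
#' @return the pruned `phylo` object.
#' @examples
#' tr <- read_newick("((A:1,B:1):2,C:3);")
#' write_newick(prune_to(tr, c("A", "C"))) # "(A:3,C:3);"
#' @export
prune_to <- function(tree, keep) {
  validate_tree(tree)
  keep <- unique(as.character(keep))
  if (length(keep) == 0L) stop("'keep' must contain at least one tip")
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown))
    stop("unknown tip labels in 'keep': ", paste(unknown, collapse = ", "))
  if (length(keep) == length(tree$tip.label)) return(tree)
  orig_root <- root_edge_len(tree)
  if (length(keep) == 1L) {
    # ape cannot collapse down to one tip; build the single-tip tree by hand
    depth <- tip_depth(tree, keep)
    out <- structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                          tip.label = keep, Nnode = 1L,
                          edge.length = depth),
                     class = "phylo", order = "cladewise")
    if (orig_root > 0) out$root.edge <- orig_root
    return(out)
  }
  out <- ape::keep.tip(tree, keep)
  # the stem from the new root back to the original root becomes the root
  # edge, so surviving tips keep their full depth
  stem <- tip_depth(tree, keep[1L]) - tip_depth(out, keep[1L]) + orig_root
  if (stem > 1e-12) out$root.edge <- stem
  out
}

# depth (root-to-tip path length, excluding root edge) of one tip
tip_depth <- function(tree, tip) {
  i <- match(tip, tree$tip.label)
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  elen <- numeric(max(tree$edge))
  elen[tree$edge[, 2L]] <- tree$edge.length
  root <- length(tree$tip.label) + 1L
  d <- 0
  v <- i
  while (v != root) {
    d <- d + elen[v]
    v <- parent[v]
  }
  d
}

#' Patristic distance between two tips
#'
#' Sum of branch lengths on the path between tips `a` and `b` through their
#' most recent common ancestor. Symmetric, and zero when `a == b`.
#'
#' @param tree a `phylo` object.
#' @param a,b tip labels.
#' @return distance in Myr.
#' @export
patristic_distance <- function(tree, a, b) {
  validate_tree(tree)
  for (x in c(a, b))
    if (!x %in% tree$tip.label) stop("unknown tip: ", x)
  if (a == b) return(0)
  m <- ape::getMRCA(tree, c(a, b))
  depths <- ape::node.depth.edgelength(tree)
  depths[match(a, tree$tip.label)] + depths[match(b, tree$tip.label)] -
    2 * depths[m]
}

# shared walker for both ED variants:
# per tip, accumulate length(edge)/divisor walking rootwards, where the
# divisor grows according to `step(node)` each time an internal node is
# passed. The root edge (if any) is apportioned like any other edge.
ed_walk <- function(tree, divisor_step) {
  ntip <- length(tree$tip.label)
  nnode <- max(tree$edge)
  parent <- integer(nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  elen <- numeric(nnode)
  elen[tree$edge[, 2L]] <- tree$edge.length
  root <- ntip + 1L
  step <- divisor_step(tree)
  re <- root_edge_len(tree)
  ed <- numeric(ntip)
  for (i in seq_len(ntip)) {
    div <- 1
    v <- i
    acc <- 0
    while (v != root) {
      acc <- acc + elen[v] / div
      div <- div * step[parent[v]]
      v <- parent[v]
    }
    ed[i] <- acc + re / div
  }
  names(ed) <- tree$tip.label
  ed
}

#' Evolutionary distinctiveness, equal-splits
#'
#' Apportions the tree's total branch length among its tips by the
#' equal-splits rule: each edge on a tip's root path contributes its length
#' divided by the product of the child counts of every internal node lying
#' between that edge and the tip. A tip's pendant edge has divisor 1; at a
#' bifurcation the divisor doubles, at a k-furcation it multiplies by k. A
#' root edge, if present, is shared among all tips by the same rule. The
#' values always sum to [total_branch_length()].
#'
#' @param tree a `phylo` object.
#' @return named numeric vector of ED values (Myr), one per tip.
#' @examples
#' ed_equal_splits(read_newick("((A:1,B:1):2,C:3);")) # A 2, B 2, C 3
#' @export
ed_equal_splits <- function(tree) {
  validate_tree(tree)
  if (length(tree$tip.label) == 1L)
    return(stats::setNames(total_branch_length(tree), tree$tip.label))
  ed_walk(tree, function(tr) {
    nchild <- tabulate(tr$edge[, 1L], nbins = max(tr$edge))
    nchild
  })
}

#' Evolutionary distinctiveness, fair-proportion
#'
#' Each edge's length is divided equally among the tips that descend from
#' it. Companion metric to [ed_equal_splits()]; same sum property.
#'
#' @inheritParams ed_equal_splits
#' @return named numeric vector of ED values (Myr), one per tip.
#' @export
ed_fair_proportion <- function(tree) {
  validate_tree(tree)
  if (length(tree$tip.label) == 1L)
    return(stats::setNames(total_branch_length(tree), tree$tip.label))
  # divisor after passing node p must become the tip count below p, so the
  # multiplicative step is (tips below p) / (tips below child we came from);
  # easier to walk directly with per-node tip counts
  ntip <- length(tree$tip.label)
  nnode <- max(tree$edge)
  parent <- integer(nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  elen <- numeric(nnode)
  elen[tree$edge[, 2L]] <- tree$edge.length
  root <- ntip + 1L
  ndesc <- node_tip_counts(tree)
  re <- root_edge_len(tree)
  ed <- numeric(ntip)
  for (i in seq_len(ntip)) {
    v <- i
    acc <- 0
    while (v != root) {
      acc <- acc + elen[v] / ndesc[v]
      v <- parent[v]
    }
    ed[i] <- acc + re / ntip
  }
  names(ed) <- tree$tip.label
  ed
}

# number of descendant tips of every node (tips count themselves)
node_tip_counts <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- max(tree$edge)
  cnt <- c(rep(1L, ntip), rep(0L, nnode - ntip))
  # postorder: a child's subtree is complete before the edge above it
  for (e in ape::postorder(tree)) {
    cnt[tree$edge[e, 1L]] <- cnt[tree$edge[e, 1L]] + cnt[tree$edge[e, 2L]]
  }
  cnt
}
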