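# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals: they work
# by explicit path/pair enumeration on the raw phylo edge matrix.

# ancestor path of a tip: list of nodes from the tip up to the root
path_to_root <- function(tree, tip) {
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- length(tree$tip.label) + 1L
  v <- match(tip, tree$tip.label)
  p <- v
  while (v != root) {
    v <- parent[v]
    p <- c(p, v)
  }
  p
}

edge_len_lookup <- function(tree) {
  el <- numeric(max(tree$edge))
  el[tree$edge[, 2]] <- tree$edge.length
  el
}

# patristic distance by enumerating both root paths and trimming the
# shared suffix
oracle_patristic <- function(tree, a, b) {
  if (a == b) return(0)
  pa <- path_to_root(tree, a)
  pb <- path_to_root(tree, b)
  shared <- intersect(pa, pb)
  mrca <- shared[which.min(match(shared, pa))]
  el <- edge_len_lookup(tree)
  sum(el[pa[seq_len(match(mrca, pa) - 1L)]]) +
    sum(el[pb[seq_len(match(mrca, pb) - 1L)]])
}

# equal-splits ED by top-down edge apportionment: each edge's length is
# pushed down to the descendant tips, dividing by the child count at
# every internal node passed on the way down
oracle_equal_splits <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  el <- edge_len_lookup(tree)
  ed <- numeric(ntip)
  push <- function(node, amount) {
    if (node <= ntip) {
      ed[node] <<- ed[node] + amount
    } else {
      ch <- kids[[as.character(node)]]
      for (c_ in ch) push(c_, amount / length(ch))
    }
  }
  for (e in seq_len(nrow(tree$edge))) {
    v <- tree$edge[e, 2]
    push(v, el[v])
  }
  re <- if (is.null(tree$root.edge)) 0 else tree$root.edge
  if (re > 0) push(ntip + 1L, re)
  stats::setNames(ed, tree$tip.label)
}

# fair-proportion ED: each edge's length divided equally among its
# descendant tips
oracle_fair_proportion <- function(tree) {
  ntip <- length(tree$tip.label)
  ed <- stats::setNames(numeric(ntip), tree$tip.label)
  el <- edge_len_lookup(tree)
  for (tip in tree$tip.label) {
    p <- path_to_root(tree, tip)
    for (v in p[-length(p)]) {
      desc <- descendant_tips(tree, v)
      ed[tip] <- ed[tip] + el[v] / length(desc)
    }
  }
  re <- if (is.null(tree$root.edge)) 0 else tree$root.edge
  ed + re / ntip
}

descendant_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, descendant_tips, tree = tree))
}

# MPD by double loop over all unordered host pairs
oracle_mpd <- function(tree, hosts) {
  if (length(hosts) <= 1) return(0)
  tot <- 0; np <- 0
  for (i in seq_along(hosts)) for (j in seq_len(i - 1L)) {
    tot <- tot + oracle_patristic(tree, hosts[i], hosts[j])
    np <- np + 1L
  }
  tot / np
}

# grid-search maximiser of force-of-infection-weighted fitness
oracle_joint_optimum <- function(system, step = 1e-4) {
  vstar <- vapply(system$hosts, function(h) h$s * h$mu / (1 - h$s),
                  numeric(1))
  v <- seq(0, 2 * max(vstar), by = step)
  w <- rowSums(vapply(system$hosts,
                      function(h) h$rho * h$b * v^h$s / (h$mu + v),
                      numeric(length(v))))
  v[which.max(w)]
}

# a random network over the tips of a tree: each parasite gets a uniform
# random non-empty host subset (no phylogenetic structure; pure stress
# input for metric/trajectory checks)
random_network <- function(tree, n_parasites, statuses = NULL) {
  tips <- tree$tip.label
  edges <- do.call(rbind, lapply(seq_len(n_parasites), function(i) {
    h <- sample(tips, sample.int(length(tips), 1))
    data.frame(parasite = sprintf("p%03d", i), host = h)
  }))
  if (is.null(statuses))
    statuses <- sample(c("CR", "EN", "VU", "NT", "LC", "DD"),
                       length(tips), replace = TRUE)
  attrs <- data.frame(host = tips, iucn_status = statuses,
                      domesticated = FALSE, extinct = FALSE)
  host_parasite_network(edges, attrs)
}

toy_tree <- function() read_newick("((A:1,B:1):2,C:3);")
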