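# Parsimony gene-tree / species-tree reconciliation: LCA mapping,
# duplication/speciation labelling, path-depth loss counting, weighted cost
# (defaults: duplication 1.5, loss 1.0), NNI rearrangement of weakly
# supported edges, and Sankoff ancestral copy-number inference.

# --- small rooted-tree helpers on ape::phylo ---------------------------------

tree_parents <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  parent <- integer(n)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  parent[root_node(tree)] <- 0L
  parent
}

root_node <- function(tree) {
  setdiff(tree$edge[, 1], tree$edge[, 2])[1]
}

tree_children <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  ch <- vector("list", n)
  for (i in seq_len(nrow(tree$edge))) {
    ch[[tree$edge[i, 1]]] <- c(ch[[tree$edge[i, 1]]], tree$edge[i, 2])
  }
  ch
}

check_rooted_binary <- function(tree, what = "tree") {
  if (!ape::is.rooted(tree)) stop(what, " must be rooted")
  if (!ape::is.binary(tree)) stop(what, " must be binary (no branches were collapsed)")
  invisible(TRUE)
}

node_depths <- function(tree) {
  parent <- tree_parents(tree)
  n <- length(parent)
  depth <- integer(n)
  ord <- preorder_nodes(tree)
  for (v in ord) if (parent[v] != 0L) depth[v] <- depth[parent[v]] + 1L
  depth
}

preorder_nodes <- function(tree) {
  ch <- tree_children(tree)
  out <- integer(0)
  stack <- root_node(tree)
  while (length(stack) > 0L) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, v)
    stack <- c(stack, rev(ch[[v]]))
  }
  out
}

postorder_nodes <- function(tree) rev(preorder_nodes(tree))

# ancestor matrix: anc[[v]] = vector of ancestors of v from v up to root
ancestor_paths <- function(tree) {
  parent <- tree_parents(tree)
  lapply(seq_along(parent), function(v) {
    path <- v
    while (parent[path[length(path)]] != 0L) path <- c(path, parent[path[length(path)]])
    path
  })
}

species_lca_table <- function(tree) {
  paths <- ancestor_paths(tree)
  n <- length(paths)
  lca <- matrix(0L, n, n)
  depth <- node_depths(tree)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    common <- intersect(paths[[i]], paths[[j]])
    lca[i, j] <- common[which.max(depth[common])]
  }
  lca
}

# --- LCA mapping and event annotation ----------------------------------------

#' LCA mapping of a gene tree into a species tree
#'
#' Each gene-tree node is mapped to the last common ancestor (in the species
#' tree) of the species of its leaf descendants.
#'
#' @param gene_tree Rooted binary `phylo`.
#' @param species_tree Rooted binary `phylo` with unique leaf labels.
#' @param leaf_species Named character vector mapping every gene-tree leaf
#'   label to a species-tree leaf label. Default: the part of the gene leaf
#'   label before the last underscore (the simulator's `species_copy`
#'   convention).
#' @return Integer vector of species-tree node indices, one per gene-tree
#'   node (tips first, ape numbering).
#' @export
lca_map <- function(gene_tree, species_tree, leaf_species = NULL) {
  check_rooted_binary(gene_tree, "gene tree")
  check_rooted_binary(species_tree, "species tree")
  if (is.null(leaf_species)) {
    leaf_species <- stats::setNames(sub("_[^_]*$", "", gene_tree$tip.label),
                                    gene_tree$tip.label)
  }
  unmapped <- setdiff(gene_tree$tip.label, names(leaf_species))
  if (length(unmapped) > 0L) stop("unmapped gene leaves: ", paste(unmapped, collapse = ", "))
  bad <- setdiff(unname(leaf_species[gene_tree$tip.label]), species_tree$tip.label)
  if (length(bad) > 0L) stop("species not in species tree: ", paste(unique(bad), collapse = ", "))

  lca <- species_lca_table(species_tree)
  sp_leaf_idx <- stats::setNames(seq_len(ape::Ntip(species_tree)), species_tree$tip.label)
  ng <- ape::Ntip(gene_tree) + gene_tree$Nnode
  M <- integer(ng)
  ch <- tree_children(gene_tree)
  for (v in postorder_nodes(gene_tree)) {
    if (v <= ape::Ntip(gene_tree)) {
      M[v] <- sp_leaf_idx[[leaf_species[[gene_tree$tip.label[v]]]]]
    } else {
      kids <- ch[[v]]
      m <- M[kids[1]]
      for (k in kids[-1]) m <- lca[m, M[k]]
      M[v] <- m
    }
  }
  M
}

#' Annotate duplication/speciation events and count losses
#'
#' Under a species mapping `M`, an internal gene-tree node is a duplication
#' iff it maps to the same species node as one of its children. Losses on a
#' gene-tree edge (u, v) follow the path-depth rule: with k = number of
#' species-tree edges between M(u) and M(v), losses = k - 1 for a speciation
#' parent and k for a duplication parent (0 when k = 0).
#'
#' @param gene_tree,species_tree Rooted binary `phylo` trees.
#' @param M Mapping from [lca_map()] (computed if NULL).
#' @param leaf_species Passed to [lca_map()] when `M` is NULL.
#' @param dup_cost,loss_cost Event costs (defaults 1.5 and 1.0).
#' @return List of class `reconciled_tree`: `events` (per internal node),
#'   `edge_losses` (per gene-tree edge), `n_dup`, `n_loss`, `cost`, plus the
#'   inputs.
#' @export
annotate_events <- function(gene_tree, species_tree, M = NULL,
                            leaf_species = NULL, dup_cost = 1.5, loss_cost = 1.0) {
  if (dup_cost <= 0 || loss_cost <= 0) stop("costs must be positive")
  if (is.null(M)) M <- lca_map(gene_tree, species_tree, leaf_species)
  ntip <- ape::Ntip(gene_tree)
  ch <- tree_children(gene_tree)
  depth_s <- node_depths(species_tree)

  n_nodes <- ntip + gene_tree$Nnode
  events <- rep(NA_character_, n_nodes)
  for (v in (ntip + 1L):n_nodes) {
    events[v] <- if (any(M[ch[[v]]] == M[v])) "duplication" else "speciation"
  }
  edge_losses <- integer(nrow(gene_tree$edge))
  for (i in seq_len(nrow(gene_tree$edge))) {
    u <- gene_tree$edge[i, 1]; v <- gene_tree$edge[i, 2]
    k <- depth_s[M[v]] - depth_s[M[u]]
    edge_losses[i] <- if (events[u] == "duplication") k else max(0L, k - 1L)
  }
  n_dup <- sum(events == "duplication", na.rm = TRUE)
  n_loss <- sum(edge_losses)
  structure(list(gene_tree = gene_tree, species_tree = species_tree, M = M,
                 events = events, edge_losses = edge_losses,
                 n_dup = n_dup, n_loss = n_loss,
                 cost = dup_cost * n_dup + loss_cost * n_loss,
                 dup_cost = dup_cost, loss_cost = loss_cost),
            class = "reconciled_tree")
}

#' @export
print.reconciled_tree <- function(x, ...) {
  cat("Reconciled gene tree:", ape::Ntip(x$gene_tree), "leaves\n")
  cat(sprintf("  duplications: %d  losses: %d  cost: %.2f (dup %.2f, loss %.2f)\n",
              x$n_dup, x$n_loss, x$cost, x$dup_cost, x$loss_cost))
  invisible(x)
}

#' Reconcile a gene tree against a species tree
#'
#' Convenience wrapper: LCA mapping followed by event annotation.
#'
#' @inheritParams annotate_events
#' @return A `reconciled_tree`.
#' @export
reconcile_tree <- function(gene_tree, species_tree, leaf_species = NULL,
                           dup_cost = 1.5, loss_cost = 1.0) {
  annotate_events(gene_tree, species_tree, leaf_species = leaf_species,
                  dup_cost = dup_cost, loss_cost = loss_cost)
}

#' Canonical (sorted) newick topology string
#'
#' Labels-only newick with children sorted lexicographically at every node;
#' used for deterministic tie-breaking and topology comparison.
#'
#' @param tree `phylo`.
#' @return Character scalar ending in `";"`.
#' @export
canonical_topology <- function(tree) canonical_newick(tree)

# canonical topology string (labels only), used for deterministic tie-breaks
canonical_newick <- function(tree) {
  ch <- tree_children(tree)
  build <- function(v) {
    if (v <= ape::Ntip(tree)) return(tree$tip.label[v])
    parts <- sort(vapply(ch[[v]], build, character(1)))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(build(root_node(tree)), ";")
}

# apply one rooted NNI: for internal edge (u, v), swap child `ci` of v with
# the sibling subtree w of v. Returns a new phylo.
apply_nni <- function(tree, u, v, ci) {
  ch <- tree_children(tree)
  w <- setdiff(ch[[u]], v)[1]
  edge <- tree$edge
  row_uw <- which(edge[, 1] == u & edge[, 2] == w)
  row_vc <- which(edge[, 1] == v & edge[, 2] == ci)
  edge[row_uw, 2] <- ci
  edge[row_vc, 2] <- w
  tree$edge <- edge
  tree <- ape::reorder.phylo(tree, "cladewise")
  tree
}

#' Rearrange weakly supported edges to minimise reconciliation cost
#'
#' Greedy search over NNI moves restricted to internal edges whose bootstrap
#' support (internal node label of the child node) is below the threshold.
#' The move that most reduces the weighted duplication-loss cost is applied
#' repeatedly until no improvement remains; equal-cost candidates are
#' resolved by the lexicographically smallest canonical newick.
#'
#' @param gene_tree Rooted binary `phylo` with `node.label` supports in
#'   `[0, 1]` (empty/NA labels are treated as strong).
#' @param species_tree Rooted binary `phylo`.
#' @param leaf_species Optional leaf -> species map (see [lca_map()]).
#' @param support_threshold Edges with support below this may be rearranged
#'   (default 0.9).
#' @param dup_cost,loss_cost Costs (defaults 1.5, 1.0).
#' @return List with `tree` (possibly rearranged) and `reconciliation`
#'   (a `reconciled_tree`).
#' @export
rearrange_weak_edges <- function(gene_tree, species_tree, leaf_species = NULL,
                                 support_threshold = 0.9,
                                 dup_cost = 1.5, loss_cost = 1.0) {
  if (support_threshold < 0 || support_threshold > 1) stop("threshold must be in [0,1]")
  check_rooted_binary(gene_tree, "gene tree")
  cost_of <- function(tr) {
    annotate_events(tr, species_tree, leaf_species = leaf_species,
                    dup_cost = dup_cost, loss_cost = loss_cost)$cost
  }
  current <- gene_tree
  current_cost <- cost_of(current)
  repeat {
    ntip <- ape::Ntip(current)
    labels <- current$node.label
    rn <- root_node(current)
    ch <- tree_children(current)
    candidates <- list()
    for (v in (ntip + 1L):(ntip + current$Nnode)) {
      if (v == rn) next
      sup <- suppressWarnings(as.numeric(labels[v - ntip]))
      if (is.na(sup) || sup >= support_threshold) next
      u <- tree_parents(current)[v]
      for (ci in ch[[v]]) {
        cand <- apply_nni(current, u, v, ci)
        candidates[[length(candidates) + 1L]] <- cand
      }
    }
    if (length(candidates) == 0L) break
    costs <- vapply(candidates, cost_of, numeric(1))
    best <- min(costs)
    if (best >= current_cost) break
    ties <- which(costs == best)
    if (length(ties) > 1L) {
      keys <- vapply(candidates[ties], canonical_newick, character(1))
      ties <- ties[order(keys)][1]
    }
    current <- candidates[[ties[1]]]
    current_cost <- best
  }
  list(tree = current,
       reconciliation = annotate_events(current, species_tree,
                                        leaf_species = leaf_species,
                                        dup_cost = dup_cost, loss_cost = loss_cost))
}

#' Ancestral copy numbers and per-branch gains/losses (Sankoff parsimony)
#'
#' Minimum-change integer ancestral states under unit cost per copy-number
#' change; per-branch delta = child state - parent state. Equally
#' parsimonious ancestral states are resolved toward the smallest state.
#'
#' @param copy_numbers Named integer vector: species -> extant copy number
#'   (>= 0); must cover all species-tree leaves.
#' @param species_tree Rooted binary `phylo`.
#' @return List with `ancestral` (state per node), `deltas` (data.frame per
#'   edge: parent, child, delta), `total_change`.
#' @export
infer_gains_losses <- function(copy_numbers, species_tree) {
  check_rooted_binary(species_tree, "species tree")
  tips <- species_tree$tip.label
  miss <- setdiff(tips, names(copy_numbers))
  if (length(miss) > 0L) stop("missing copy numbers for: ", paste(miss, collapse = ", "))
  if (any(copy_numbers < 0)) stop("copy numbers must be >= 0")
  states <- 0:max(copy_numbers)
  ns <- length(states)
  ntip <- ape::Ntip(species_tree)
  nn <- ntip + species_tree$Nnode
  ch <- tree_children(species_tree)
  bigM <- 1e9
  costm <- matrix(bigM, nn, ns)
  for (i in seq_len(ntip)) {
    costm[i, which(states == copy_numbers[[tips[i]]])] <- 0
  }
  trans <- abs(outer(states, states, "-"))  # cost of parent state s -> child state t
  for (v in postorder_nodes(species_tree)) {
    if (v <= ntip) next
    acc <- numeric(ns)
    for (k in ch[[v]]) {
      # for each parent state: min over child states of (trans + child cost)
      acc <- acc + apply(trans + rep(costm[k, ], each = ns), 1, min)
    }
    costm[v, ] <- acc
  }
  anc <- integer(nn)
  rn <- root_node(species_tree)
  anc[rn] <- states[which.min(costm[rn, ])]
  for (v in preorder_nodes(species_tree)) {
    for (k in ch[[v]]) {
      tot <- trans[which(states == anc[v]), ] + costm[k, ]
      anc[k] <- states[which.min(tot)]
    }
  }
  deltas <- data.frame(parent = species_tree$edge[, 1],
                       child = species_tree$edge[, 2],
                       delta = anc[species_tree$edge[, 2]] - anc[species_tree$edge[, 1]])
  list(ancestral = anc, deltas = deltas, total_change = sum(abs(deltas$delta)))
}
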