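# Independent oracles used across the suite. Each is written from first
# principles (enumeration, closed form, series summation) and kept separate
# from the implementation paths it checks.

GC <- Biostrings::GENETIC_CODE
STOPS <- c("TAA", "TAG", "TGA")
NUC4 <- c("A", "C", "G", "T")

oracle_sense_codons <- function() {
  all <- sort(apply(expand.grid(NUC4, NUC4, NUC4)[, 3:1], 1, paste0, collapse = ""))
  setdiff(all, STOPS)
}

# NG86 site counts by explicit neighbour enumeration
oracle_ng86_sites <- function(codon) {
  s <- 0
  for (pos in 1:3) {
    syn <- 0; valid <- 0
    for (nuc in setdiff(NUC4, substr(codon, pos, pos))) {
      nb <- codon
      substr(nb, pos, pos) <- nuc
      if (nb %in% STOPS) next
      valid <- valid + 1
      if (GC[[nb]] == GC[[codon]]) syn <- syn + 1
    }
    if (valid > 0) s <- s + syn / valid
  }
  c(s = s, n = 3 - s)
}

# pathway-averaged differences by recursive pathway enumeration
oracle_ng86_diffs <- function(a, b) {
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (length(pos) == 0) return(c(sd = 0, nd = 0))
  walk <- function(cur, remaining) {
    if (length(remaining) == 0) return(list(c(0, 0)))
    out <- list()
    for (i in seq_along(remaining)) {
      p <- remaining[i]
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (nxt %in% STOPS) next
      step <- if (GC[[cur]] == GC[[nxt]]) c(1, 0) else c(0, 1)
      for (tail in walk(nxt, remaining[-i])) {
        out[[length(out) + 1]] <- step + tail
      }
    }
    out
  }
  paths <- walk(a, pos)
  if (length(paths) == 0) stop("no valid pathway")
  avg <- Reduce(`+`, paths) / length(paths)
  c(sd = avg[1], nd = avg[2])
}

# matrix exponential by scaled series summation (independent of eigen path)
oracle_expm <- function(Q, t) {
  n <- nrow(Q)
  k <- max(1L, ceiling(log2(max(1, t * max(abs(diag(Q)))) * 4)))
  A <- Q * t / 2^k
  P <- diag(n)
  term <- diag(n)
  for (i in 1:30) {
    term <- term %*% A / i
    P <- P + term
  }
  for (i in seq_len(k)) P <- P %*% P
  P
}

# exhaustive pruning oracle: sum over all internal-state assignments.
# tree: ape phylo (rooted binary), states: integer matrix rows=taxa (by tip
# label), P_list: per-edge 61x61 matrices, pi: root frequencies.
oracle_tree_lik <- function(tree, states, P_list, pi) {
  ntip <- ape::Ntip(tree)
  nint <- tree$Nnode
  nsite <- ncol(states)
  rt <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  grid <- as.matrix(expand.grid(rep(list(1:61), nint)))  # one row per joint
  lik <- numeric(nsite)
  for (site in seq_len(nsite)) {
    state_of <- function(v) {
      if (v <= ntip) rep(states[tree$tip.label[v], site], nrow(grid))
      else grid[, v - ntip]
    }
    pr <- pi[state_of(rt)]
    for (ei in seq_len(nrow(tree$edge))) {
      u <- tree$edge[ei, 1]; v <- tree$edge[ei, 2]
      pr <- pr * P_list[[ei]][cbind(state_of(u), state_of(v))]
    }
    lik[site] <- sum(pr)
  }
  sum(log(lik))
}

# brute-force reconciliation: minimum weighted cost over all ancestrally
# consistent mappings; events and losses computed from first principles.
oracle_reconcile <- function(gene_tree, species_tree, leaf_species,
                             dup_cost = 1.5, loss_cost = 1.0) {
  ntip_g <- ape::Ntip(gene_tree)
  nn_g <- ntip_g + gene_tree$Nnode
  nn_s <- ape::Ntip(species_tree) + species_tree$Nnode
  parent_s <- integer(nn_s)
  parent_s[species_tree$edge[, 2]] <- species_tree$edge[, 1]
  rt_s <- setdiff(species_tree$edge[, 1], species_tree$edge[, 2])[1]
  anc_of <- function(v) {  # v and its ancestors
    out <- v
    while (out[length(out)] != rt_s) out <- c(out, parent_s[out[length(out)]])
    out
  }
  is_anc <- function(a, d) a %in% anc_of(d)  # a ancestor-or-equal of d
  dist_s <- function(a, d) which(anc_of(d) == a) - 1L  # edges from a down to d
  children_g <- vector("list", nn_g)
  for (i in seq_len(nrow(gene_tree$edge))) {
    children_g[[gene_tree$edge[i, 1]]] <- c(children_g[[gene_tree$edge[i, 1]]],
                                            gene_tree$edge[i, 2])
  }
  sp_idx <- setNames(seq_len(ape::Ntip(species_tree)), species_tree$tip.label)
  leaf_map <- sp_idx[leaf_species[gene_tree$tip.label]]
  # species-child of s on the path toward descendant d
  child_toward <- function(s, d) {
    path <- anc_of(d)
    path[which(path == s) - 1L]
  }
  cost_of_mapping <- function(M) {
    ndup <- 0L; nloss <- 0L
    for (v in (ntip_g + 1):nn_g) {
      kids <- children_g[[v]]
      for (k in kids) if (!is_anc(M[v], M[k])) return(NULL)
      # speciation iff children map into distinct child-subtrees of M(v)
      sides <- vapply(kids, function(k) {
        if (M[k] == M[v]) NA_integer_ else child_toward(M[v], M[k])
      }, integer(1))
      is_spec <- !anyNA(sides) && length(unique(sides)) == length(sides)
      if (!is_spec) ndup <- ndup + 1L
      for (k in kids) {
        s0 <- if (is_spec) child_toward(M[v], M[k]) else M[v]
        nloss <- nloss + dist_s(s0, M[k])
      }
    }
    list(ndup = ndup, nloss = nloss,
         cost = dup_cost * ndup + loss_cost * nloss)
  }
  int_nodes <- (ntip_g + 1):nn_g
  choices <- rep(list(seq_len(nn_s)), length(int_nodes))
  best <- NULL
  grid <- as.matrix(expand.grid(choices))
  for (g in seq_len(nrow(grid))) {
    M <- integer(nn_g)
    M[seq_len(ntip_g)] <- leaf_map
    M[int_nodes] <- grid[g, ]
    r <- cost_of_mapping(M)
    if (!is.null(r) && (is.null(best) || r$cost < best$cost)) best <- r
  }
  best
}

# exhaustive Sankoff oracle over integer ancestral states
oracle_sankoff <- function(copy_numbers, species_tree, max_state = NULL) {
  tips <- species_tree$tip.label
  if (is.null(max_state)) max_state <- max(copy_numbers)
  ntip <- ape::Ntip(species_tree)
  nint <- species_tree$Nnode
  grid <- as.matrix(expand.grid(rep(list(0:max_state), nint)))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    st <- c(copy_numbers[tips], grid[g, ])
    tot <- sum(abs(st[species_tree$edge[, 2]] - st[species_tree$edge[, 1]]))
    best <- min(best, tot)
  }
  best
}

# random rooted binary tree with branch lengths
random_rooted_tree <- function(n_leaves, labels = NULL) {
  tr <- ape::rtree(n_leaves, rooted = TRUE)
  if (!is.null(labels)) tr$tip.label <- labels
  tr
}

# a fixed codon-reverse-translation (one codon per amino acid)
AA2CODON <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
              Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
              L = "CTG", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
              S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

reverse_translate <- function(protein) {
  paste0(AA2CODON[strsplit(protein, "")[[1]]], collapse = "")
}

# a synthetic 7-TM chemoreceptor-like protein: 21-aa hydrophobic blocks
# separated by 15-aa acidic linkers, with an N-terminal Met
synthetic_7tm_protein <- function() {
  blocks <- rep(c(strrep("L", 21), strrep("D", 15)), 7)[1:13]
  paste0("M", paste0(blocks, collapse = ""))
}
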