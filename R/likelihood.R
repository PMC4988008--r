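# Felsenstein pruning over the 61 sense-codon states, with per-node
# rescaling, site-pattern compression, site-class mixtures, and
# outside-subtree ("flow") caches that make per-branch refits cheap when
# only the focal branch's model changes.

# Convert a named character vector of (gap-free) DNA strings to a codon
# matrix (rows = sequences, columns = codon sites).
#' @rdname codon_alignment
#' @param dna Named character vector of equal-length DNA strings.
#' @export
codon_matrix_from_dna <- function(dna) {
  if (is.null(names(dna)) || any(names(dna) == "")) stop("sequences must be named")
  rows <- lapply(dna, split_codons)
  len <- unique(lengths(rows))
  if (length(len) != 1L) stop("sequences differ in length")
  out <- do.call(rbind, rows)
  rownames(out) <- names(dna)
  out
}

#' Codon alignment containers
#'
#' A codon alignment is a character matrix of 3-letter codons with one row
#' per sequence (rownames are sequence names) and one column per codon site.
#'
#' @name codon_alignment
NULL

# internal: compress an integer state matrix into unique patterns
compress_patterns <- function(states) {
  keys <- apply(states, 2, paste, collapse = ",")
  uk <- unique(keys)
  idx <- match(keys, uk)
  first <- match(uk, keys)
  list(states = states[, first, drop = FALSE],
       weights = as.vector(table(factor(idx, levels = seq_along(uk)))),
       site_to_pattern = idx)
}

# internal: one pruning pass. P_of(edge_row) returns the 61x61 matrix for
# that edge. Returns per-pattern log-likelihoods plus (optionally) the node
# partials and per-node log-scale vectors for flow computation.
prune_loglik <- function(tree, states_pat, P_of, pi, keep_partials = FALSE) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  npat <- ncol(states_pat)
  ch_edges <- vector("list", nn)   # edge rows by parent node
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    ch_edges[[p]] <- c(ch_edges[[p]], i)
  }
  down <- vector("list", nn)
  logsc <- vector("list", nn)
  zero <- rep(0, npat)
  for (v in postorder_nodes(tree)) {
    if (v <= ntip) {
      L <- matrix(0, 61, npat)
      L[cbind(states_pat[rownames(states_pat) == tree$tip.label[v], ], seq_len(npat))] <- 1
      down[[v]] <- L
      logsc[[v]] <- zero
    } else {
      L <- matrix(1, 61, npat)
      sc <- zero
      for (ei in ch_edges[[v]]) {
        k <- tree$edge[ei, 2]
        L <- L * (P_of(ei) %*% down[[k]])
        sc <- sc + logsc[[k]]
      }
      mx <- apply(L, 2, max)
      mx[mx <= 0] <- 1
      down[[v]] <- L / rep(mx, each = 61)
      logsc[[v]] <- sc + log(mx)
    }
  }
  rt <- root_node(tree)
  lik <- colSums(pi * down[[rt]])
  out <- list(log_pat = log(lik) + logsc[[rt]])
  if (keep_partials) {
    out$down <- down
    out$logsc <- logsc
    out$ch_edges <- ch_edges
  }
  out
}

#' Log-likelihood of a codon alignment on a tree under a site-class mixture
#'
#' Felsenstein pruning over 61 codon states. Each mixture component supplies
#' a weight, a background omega (all branches) and optionally a foreground
#' omega applying to one designated branch. Per-site log-likelihoods and
#' per-component site likelihoods are returned for posterior computation.
#'
#' @param alignment Codon matrix (see [codon_alignment]); rownames must match
#'   the tree's tip labels.
#' @param tree Rooted `phylo` with branch lengths (expected substitutions per
#'   codon site).
#' @param kappa Transition/transversion ratio.
#' @param pi Codon frequencies (61); default F3x4 from the alignment.
#' @param components List of components `list(weight, omega, omega_fg)`
#'   (omega_fg defaults to omega). Weights must sum to 1.
#' @param fg_edge Edge row index (in `tree$edge`) of the foreground branch,
#'   or NULL.
#' @return List with `loglik`, `site_loglik` (per codon site),
#'   `comp_site_loglik` (components x sites matrix of per-component site
#'   log-likelihoods), `pi`.
#' @export
tree_loglik <- function(alignment, tree, kappa, pi = NULL,
                        components = list(list(weight = 1, omega = 1)),
                        fg_edge = NULL) {
  missing_taxa <- setdiff(tree$tip.label, rownames(alignment))
  extra <- setdiff(rownames(alignment), tree$tip.label)
  if (length(missing_taxa) > 0L || length(extra) > 0L) {
    stop("alignment/tree name mismatch; missing from alignment: ",
         paste(missing_taxa, collapse = ", "), "; not in tree: ",
         paste(extra, collapse = ", "))
  }
  if (any(tree$edge.length < 0)) stop("branch lengths must be >= 0")
  w <- vapply(components, function(cc) cc$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-8) stop("component weights must sum to 1")
  if (is.null(pi)) pi <- f3x4_frequencies(alignment)
  states <- matrix(codon_index(alignment), nrow(alignment), ncol(alignment),
                   dimnames = dimnames(alignment))
  pat <- compress_patterns(states)
  npat <- ncol(pat$states)

  # one shared normalisation across classes (background mixture flux)
  mu <- mixture_flux(kappa, vapply(components, function(cc) cc$omega, numeric(1)),
                     w, pi)
  comp_log_pat <- matrix(NA_real_, length(components), npat)
  for (ci in seq_along(components)) {
    cc <- components[[ci]]
    om_bg <- cc$omega
    om_fg <- if (is.null(cc$omega_fg)) om_bg else cc$omega_fg
    eig_bg <- mg94_eigen(build_mg94(kappa, om_bg, pi, flux = mu))
    eig_fg <- if (om_fg == om_bg) eig_bg else mg94_eigen(build_mg94(kappa, om_fg, pi, flux = mu))
    P_cache <- vector("list", nrow(tree$edge))
    P_of <- function(ei) {
      if (is.null(P_cache[[ei]])) {
        eg <- if (!is.null(fg_edge) && ei == fg_edge) eig_fg else eig_bg
        P_cache[[ei]] <<- transition_probs(eg, tree$edge.length[ei])
      }
      P_cache[[ei]]
    }
    comp_log_pat[ci, ] <- prune_loglik(tree, pat$states, P_of, pi)$log_pat
  }
  # mixture via log-sum-exp
  mx <- apply(comp_log_pat, 2, max)
  mix_pat <- mx + log(colSums(w * exp(comp_log_pat - rep(mx, each = length(w)))))
  list(loglik = sum(pat$weights * mix_pat),
       site_loglik = mix_pat[pat$site_to_pattern],
       comp_site_loglik = comp_log_pat[, pat$site_to_pattern, drop = FALSE],
       pi = pi)
}

# --- edge-partial (flow) caches ---------------------------------------------

# Build, under a single background model, everything needed to recompute the
# likelihood when only one branch's substitution model is replaced:
# for each edge e = (u, v): per-pattern log-lik
#   L_pat(P) = log(colSums(A_e * (P %*% down_v))) + logsc
# where A_e is the outside ("flow") partial at u excluding v's subtree.
build_edge_caches <- function(tree, states_pat, eig_bg, pi) {
  nE <- nrow(tree$edge)
  P_list <- lapply(seq_len(nE), function(ei) transition_probs(eig_bg, tree$edge.length[ei]))
  res <- prune_loglik(tree, states_pat, function(ei) P_list[[ei]], pi,
                      keep_partials = TRUE)
  ntip <- ape::Ntip(tree)
  npat <- ncol(states_pat)
  rt <- root_node(tree)
  edge_parent <- tree$edge[, 1]
  edge_child <- tree$edge[, 2]
  parent_edge_of <- integer(ape::Ntip(tree) + tree$Nnode)
  parent_edge_of[edge_child] <- seq_len(nE)

  A <- vector("list", nE)       # flow matrices per edge
  A_logsc <- vector("list", nE)
  # pre-order over edges
  ord <- order(node_depths(tree)[edge_child])
  for (ei in ord) {
    u <- edge_parent[ei]; v <- edge_child[ei]
    sib_edges <- setdiff(res$ch_edges[[u]], ei)
    M <- matrix(1, 61, npat)
    sc <- rep(0, npat)
    for (se in sib_edges) {
      s <- edge_child[se]
      M <- M * (P_list[[se]] %*% res$down[[s]])
      sc <- sc + res$logsc[[s]]
    }
    if (u == rt) {
      M <- M * pi
    } else {
      pe <- parent_edge_of[u]
      M <- M * crossprod(P_list[[pe]], A[[pe]])
      sc <- sc + A_logsc[[pe]]
    }
    mx <- apply(M, 2, max)
    mx[mx <= 0] <- 1
    A[[ei]] <- M / rep(mx, each = 61)
    A_logsc[[ei]] <- sc + log(mx)
  }
  list(tree = tree, pi = pi, eig_bg = eig_bg, P_list = P_list,
       down = res$down, down_logsc = res$logsc,
       A = A, A_logsc = A_logsc,
       base_log_pat = res$log_pat)
}

# per-pattern log-likelihood with edge `ei` replaced by matrix P
edge_replaced_log_pat <- function(cache, ei, P) {
  v <- cache$tree$edge[ei, 2]
  lik <- colSums(cache$A[[ei]] * (P %*% cache$down[[v]]))
  log(lik) + cache$A_logsc[[ei]] + cache$down_logsc[[v]]
}
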