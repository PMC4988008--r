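# Tree I/O and lightweight inference support, built on ape/phangorn:
# validated newick parsing/writing, discrete-gamma rate categories, JTT ML
# protein distances, neighbor joining and nonparametric bootstrap support.

#' Parse a newick string into a phylo tree
#'
#' Wraps `ape::read.tree` with validation: balanced parentheses, unique leaf
#' labels. Internal node labels are kept (they carry bootstrap supports).
#'
#' @param text Newick string.
#' @return An `ape::phylo` object.
#' @export
parse_newick <- function(text) {
  opens <- lengths(regmatches(text, gregexpr("\\(", text)))
  closes <- lengths(regmatches(text, gregexpr("\\)", text)))
  if (opens != closes) {
    stop("unbalanced parentheses in newick (", opens, " '(' vs ", closes, " ')')")
  }
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("failed to parse newick")
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  tr
}

#' Write a phylo tree as newick text
#'
#' @param tree `phylo` object.
#' @param digits Significant digits for branch lengths (default 10).
#' @return Newick string (with trailing semicolon).
#' @export
write_newick <- function(tree, digits = 10) {
  ape::write.tree(tree, digits = digits)
}

#' Discrete-gamma rate categories
#'
#' Equal-probability discretisation of a Gamma(shape, rate = shape)
#' distribution (mean 1); each category rate is the category mean, and rates
#' are renormalised to mean exactly 1.
#'
#' @param alpha Gamma shape (> 0).
#' @param k Number of categories (default 5).
#' @return List with `alpha`, `k` and `rates` (increasing, mean 1).
#' @export
discrete_gamma <- function(alpha, k = 5L) {
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be > 0")
  if (k < 1L) stop("k must be >= 1")
  b <- stats::qgamma(seq(0, 1, length.out = k + 1L), shape = alpha, rate = alpha)
  # mean within each slice: k * (F_{alpha+1}(b_{i+1}) - F_{alpha+1}(b_i))
  fr <- stats::pgamma(b, shape = alpha + 1, rate = alpha)
  rates <- k * diff(fr)
  rates <- rates / mean(rates)
  list(alpha = alpha, k = k, rates = rates)
}

#' Maximum-likelihood JTT distance between two aligned proteins
#'
#' Gap-containing columns are removed (complete deletion), then the
#' one-parameter ML distance under the JTT model, optionally gamma-mixed, is
#' computed via `phangorn::dist.ml`. Distances are capped.
#'
#' @param a,b Aligned protein strings of equal length.
#' @param gamma Optional result of [discrete_gamma()] for rate heterogeneity.
#' @param max_dist Cap on the returned distance (default 10).
#' @return Numeric distance (expected substitutions per site).
#' @export
jtt_ml_distance <- function(a, b, gamma = NULL, max_dist = 10) {
  va <- strsplit(toupper(a), "")[[1]]
  vb <- strsplit(toupper(b), "")[[1]]
  if (length(va) != length(vb)) stop("sequences must be aligned (equal length)")
  keep <- va != "-" & vb != "-"
  if (!any(keep)) stop("no shared (gap-free) columns")
  dat <- phangorn::phyDat(rbind(a = va[keep], b = vb[keep]), type = "AA")
  d <- if (is.null(gamma)) {
    phangorn::dist.ml(dat, model = "JTT")
  } else {
    phangorn::dist.ml(dat, model = "JTT", k = gamma$k, shape = gamma$alpha)
  }
  min(as.numeric(d)[1], max_dist)
}

#' Neighbor-joining tree from a distance matrix
#'
#' @param d Symmetric numeric matrix with zero diagonal (row/col names are
#'   taxon labels).
#' @return Unrooted `phylo`; negative branch lengths are clamped to zero with
#'   a warning.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix is not symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero")
  tr <- ape::nj(as.dist(d))
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch lengths clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Bootstrap support by site resampling
#'
#' Resamples alignment columns with replacement, rebuilds a tree per
#' replicate with `builder`, and reports for each internal edge of the
#' reference tree the fraction of replicates containing its bipartition.
#'
#' @param alignment Character matrix (rows = taxa with rownames, columns =
#'   sites).
#' @param builder Function(alignment matrix) -> `phylo`.
#' @param n_reps Number of replicates (>= 1).
#' @param seed Integer seed.
#' @return The reference tree with `node.label` set to supports in `[0, 1]`
#'   (root label empty).
#' @export
bootstrap_support <- function(alignment, builder, n_reps = 100L, seed = 1L) {
  if (!is.matrix(alignment) || ncol(alignment) < 2L) {
    stop("alignment must be a matrix with >= 2 columns")
  }
  if (n_reps < 1L) stop("n_reps must be >= 1")
  set.seed(seed)
  ref <- builder(alignment)
  reps <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    cols <- sample.int(ncol(alignment), ncol(alignment), replace = TRUE)
    reps[[i]] <- builder(alignment[, cols, drop = FALSE])
  }
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(ref, reps, rooted = ape::is.rooted(ref))
  counts[is.na(counts)] <- 0
  ref$node.label <- as.character(round(counts / n_reps, 6))
  ref
}

#' Root a tree on a declared outgroup leaf
#'
#' @param tree `phylo`.
#' @param outgroup Leaf label (e.g. the Orco or Gr21a analog).
#' @return Rooted `phylo`.
#' @export
root_on_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label) stop("outgroup '", outgroup, "' not in tree")
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' A nine-species melanogaster-group-like species tree
#'
#' Fixed topology and branch lengths (expected substitutions per codon site)
#' used as the default simulation framework: an ananassae-like outgroup, a
#' suzukii-takahashii clade, and a melanogaster subgroup.
#'
#' @return Rooted binary `phylo` with 9 leaves.
#' @export
melanogaster_group_tree <- function() {
  parse_newick(paste0(
    "(Dana:0.30,(((Dsuz:0.10,Dbia:0.10):0.04,Dtak:0.14):0.10,",
    "((Dmel:0.08,(Dsim:0.04,Dsec:0.04):0.04):0.06,",
    "(Dyak:0.07,Dere:0.07):0.07):0.10):0.06);"))
}
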