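# Branch-site test for episodic diversifying selection: on one foreground
# branch a fraction p2 of sites evolves at omega2 >= 1 while remaining sites
# (and all background branches) evolve at a shared omega1. The null fixes
# omega2 = 1; the LRT null distribution is the 50:50 chi-bar mixture of a
# point mass at zero and chi-square with 1 df (omega2 sits on the boundary).

#' Fit a single-omega MG94 model (global scale, kappa, omega)
#'
#' Branch-length proportions are taken from the input tree and scaled by one
#' free multiplier; kappa and omega are shared across branches. Used to
#' anchor branch lengths and kappa before per-branch tests.
#'
#' @param alignment Codon matrix.
#' @param tree Rooted `phylo` with branch lengths.
#' @param pi Codon frequencies (default F3x4).
#' @return List with `scale`, `kappa`, `omega`, `loglik`, `tree` (rescaled),
#'   `pi`.
#' @export
fit_single_omega <- function(alignment, tree, pi = NULL) {
  if (is.null(pi)) pi <- f3x4_frequencies(alignment)
  states <- matrix(codon_index(alignment), nrow(alignment), ncol(alignment),
                   dimnames = dimnames(alignment))
  pat <- compress_patterns(states)
  negll <- function(par) {
    sc <- exp(par[1]); kp <- exp(par[2]); om <- exp(par[3])
    eig <- mg94_eigen(build_mg94(kp, om, pi))
    tr <- tree
    tr$edge.length <- tr$edge.length * sc
    P_cache <- vector("list", nrow(tr$edge))
    P_of <- function(ei) {
      if (is.null(P_cache[[ei]])) P_cache[[ei]] <<- transition_probs(eig, tr$edge.length[ei])
      P_cache[[ei]]
    }
    lp <- prune_loglik(tr, pat$states, P_of, pi)$log_pat
    -sum(pat$weights * lp)
  }
  fit <- stats::optim(c(0, log(2), log(0.3)), negll, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-8))
  sc <- exp(fit$par[1])
  out_tree <- tree
  out_tree$edge.length <- out_tree$edge.length * sc
  list(scale = sc, kappa = exp(fit$par[2]), omega = exp(fit$par[3]),
       loglik = -fit$value, tree = out_tree, pi = pi)
}

#' Branch-site fit (alternative and null) for one foreground branch
#'
#' Alternative model: background branches and a fraction `1 - p2` of
#' foreground sites at `omega1`; a fraction `p2` of foreground sites at
#' `omega2 >= 1`. Null model: identical with `omega2` fixed at 1. Branch
#' lengths and kappa are anchored by [fit_single_omega()] (or supplied), and
#' `omega1` is profiled jointly (slow path) or fixed at the gene-wide
#' single-omega estimate (fast path, used by [scan_gene_sets()]).
#'
#' @param alignment Codon matrix.
#' @param tree Rooted `phylo` with branch lengths.
#' @param fg_edge Row index of the foreground branch in `tree$edge`.
#' @param pi Codon frequencies (default F3x4).
#' @param anchor Optional result of [fit_single_omega()] to reuse.
#' @param optimize_background Jointly optimise `omega1` in both fits
#'   (default TRUE); when FALSE, `omega1` is fixed at the anchor's omega and
#'   per-branch refits use cached edge partials (fast).
#' @param omega1_max Upper bound for `omega1` (default 1, purifying-to-
#'   neutral background; set higher to free it).
#' @param omega2_max Upper bound for `omega2` (default 50).
#' @param cache Optional precomputed edge-partial cache (internal; shared
#'   across branches of the same gene set by [scan_gene_sets()]).
#' @return List of class `branch_site_fit` with `lnL_alt`, `lnL_null`,
#'   `LR`, `mle` (omega1, p2, omega2), `null_mle`, `kappa`, `scale`,
#'   `fg_edge`, `converged`, plus internals used by [site_posteriors()].
#' @export
fit_branch_site <- function(alignment, tree, fg_edge, pi = NULL, anchor = NULL,
                            optimize_background = TRUE, omega1_max = 1,
                            omega2_max = 50, cache = NULL) {
  if (nrow(alignment) < 3L) stop("need at least 3 sequences")
  if (fg_edge < 1L || fg_edge > nrow(tree$edge)) stop("foreground branch does not exist")
  if (is.null(anchor)) anchor <- fit_single_omega(alignment, tree, pi)
  pi <- anchor$pi
  tr <- anchor$tree
  kappa <- anchor$kappa

  states <- matrix(codon_index(alignment), nrow(alignment), ncol(alignment),
                   dimnames = dimnames(alignment))
  pat <- compress_patterns(states)
  wts <- pat$weights

  if (optimize_background) {
    mix_negll <- function(om1, p2, om2) {
      res <- tree_loglik(alignment, tr, kappa, pi,
                         components = list(
                           list(weight = 1 - p2, omega = om1, omega_fg = om1),
                           list(weight = p2, omega = om1, omega_fg = om2)),
                         fg_edge = fg_edge)
      -res$loglik
    }
    tf_om1 <- function(x) omega1_max * stats::plogis(x)
    tf_p2 <- function(x) stats::plogis(x)
    tf_om2 <- function(x) 1 + (omega2_max - 1) * stats::plogis(x)
    null_obj <- function(par) mix_negll(tf_om1(par[1]), tf_p2(par[2]), 1)
    alt_obj <- function(par) mix_negll(tf_om1(par[1]), tf_p2(par[2]), tf_om2(par[3]))
    starts0 <- stats::qlogis(pmin(0.999, pmax(1e-4, anchor$omega / omega1_max)))
    null_starts <- list(c(starts0, stats::qlogis(0.1)),
                        c(starts0, stats::qlogis(0.5)),
                        c(stats::qlogis(0.5), stats::qlogis(0.05)))
    best_null <- NULL
    for (s in null_starts) {
      f <- stats::optim(s, null_obj, method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-9))
      if (is.null(best_null) || f$value < best_null$value) best_null <- f
    }
    np <- best_null$par
    alt_starts <- list(c(np, stats::qlogis(1e-4)),
                       c(np[1], stats::qlogis(0.1), stats::qlogis((5 - 1) / (omega2_max - 1))),
                       c(np[1], stats::qlogis(0.05), stats::qlogis((10 - 1) / (omega2_max - 1))))
    best_alt <- NULL
    for (s in alt_starts) {
      f <- stats::optim(s, alt_obj, method = "Nelder-Mead",
                        control = list(maxit = 600, reltol = 1e-9))
      if (is.null(best_alt) || f$value < best_alt$value) best_alt <- f
    }
    lnL_null <- -best_null$value
    lnL_alt <- max(-best_alt$value, lnL_null)
    mle <- c(omega1 = tf_om1(best_alt$par[1]), p2 = tf_p2(best_alt$par[2]),
             omega2 = tf_om2(best_alt$par[3]))
    null_mle <- c(omega1 = tf_om1(best_null$par[1]), p2 = tf_p2(best_null$par[2]),
                  omega2 = 1)
    converged <- best_alt$convergence == 0 && best_null$convergence == 0
    cache <- NULL
    omega1_used <- mle[["omega1"]]
  } else {
    omega1_used <- min(anchor$omega, omega1_max)
    mu1 <- mixture_flux(kappa, omega1_used, 1, pi)
    if (is.null(cache)) {
      eig_bg <- mg94_eigen(build_mg94(kappa, omega1_used, pi, flux = mu1))
      cache <- build_edge_caches(tr, pat$states, eig_bg, pi)
    }
    base_lp <- cache$base_log_pat           # foreground at omega1
    fg_log_pat <- function(om2) {
      eig2 <- mg94_eigen(build_mg94(kappa, om2, pi, flux = mu1))
      edge_replaced_log_pat(cache, fg_edge, transition_probs(eig2, tr$edge.length[fg_edge]))
    }
    mix_nll <- function(p2, lp2) {
      mx <- pmax(base_lp, lp2)
      -sum(wts * (mx + log((1 - p2) * exp(base_lp - mx) + p2 * exp(lp2 - mx))))
    }
    # null: omega2 = 1, optimise p2 only (1-D)
    lp_neutral <- fg_log_pat(1)
    onull <- stats::optimize(function(z) mix_nll(stats::plogis(z), lp_neutral),
                             interval = c(-12, 6), tol = 1e-7)
    p2_null <- stats::plogis(onull$minimum)
    lnL_null <- max(-onull$objective, -mix_nll(1e-9, lp_neutral))
    # alternative: (p2, omega2)
    alt_obj <- function(par) {
      om2 <- 1 + (omega2_max - 1) * stats::plogis(par[2])
      mix_nll(stats::plogis(par[1]), fg_log_pat(om2))
    }
    alt_starts <- list(c(stats::qlogis(p2_null + 1e-6), stats::qlogis(1e-4)),
                       c(stats::qlogis(0.1), stats::qlogis((5 - 1) / (omega2_max - 1))),
                       c(stats::qlogis(0.05), stats::qlogis((10 - 1) / (omega2_max - 1))))
    best_alt <- NULL
    for (s in alt_starts) {
      f <- stats::optim(s, alt_obj, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-10))
      if (is.null(best_alt) || f$value < best_alt$value) best_alt <- f
    }
    lnL_alt <- max(-best_alt$value, lnL_null)
    mle <- c(omega1 = omega1_used, p2 = stats::plogis(best_alt$par[1]),
             omega2 = 1 + (omega2_max - 1) * stats::plogis(best_alt$par[2]))
    null_mle <- c(omega1 = omega1_used, p2 = p2_null, omega2 = 1)
    converged <- best_alt$convergence == 0
  }
  LR <- max(0, 2 * (lnL_alt - lnL_null))
  structure(list(lnL_alt = lnL_alt, lnL_null = lnL_null, LR = LR,
                 mle = mle, null_mle = null_mle, kappa = kappa,
                 scale = anchor$scale, omega1 = omega1_used,
                 fg_edge = fg_edge, converged = converged,
                 tree = tr, pi = pi, alignment = alignment,
                 omega2_max = omega2_max),
            class = "branch_site_fit")
}

#' @export
print.branch_site_fit <- function(x, ...) {
  cat("Branch-site fit, foreground edge", x$fg_edge, "\n")
  cat(sprintf("  lnL(alt) = %.4f  lnL(null) = %.4f  LR = %.4f\n",
              x$lnL_alt, x$lnL_null, x$LR))
  cat(sprintf("  omega1 = %.4f  p2 = %.4f (%.1f%%)  omega2 = %.3f\n",
              x$mle[["omega1"]], x$mle[["p2"]], 100 * x$mle[["p2"]],
              x$mle[["omega2"]]))
  cat(sprintf("  p (chi-bar) = %.5f%s\n", lrt_pvalue(x$LR),
              if (!x$converged) "  [not converged]" else ""))
  invisible(x)
}

#' LRT p-value under the chi-bar boundary null
#'
#' With omega2 on the boundary of the alternative (omega2 = 1), the LRT null
#' is the 50:50 mixture of a point mass at 0 and chi-square(1):
#' `p = 0.5 * P(chisq_1 >= LR)` for LR > 0 and p = 1 at LR = 0. A plain
#' chi-square(1) null is available as a conservative switch.
#'
#' @param LR Likelihood-ratio statistic(s), >= 0 (values within -1e-6
#'   clamped).
#' @param null `"chibar"` (default) or `"chisq"`.
#' @return p-value(s).
#' @export
lrt_pvalue <- function(LR, null = c("chibar", "chisq")) {
  null <- match.arg(null)
  if (any(LR < -1e-6)) stop("negative LR")
  LR <- pmax(0, LR)
  tail <- stats::pchisq(LR, df = 1, lower.tail = FALSE)
  if (null == "chibar") ifelse(LR <= 0, 1, 0.5 * tail) else tail
}

#' Holm-Bonferroni step-down adjusted p-values
#'
#' Controls the family-wise error rate within a gene set.
#'
#' @param p Vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values (same order as input).
#' @export
holm_bonferroni <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "holm")
}

#' Benjamini-Hochberg step-up q-values
#'
#' Controls the false discovery rate across gene sets.
#'
#' @param p Vector of raw (or within-set adjusted) p-values.
#' @return q-values (same order as input).
#' @export
benjamini_hochberg <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Per-site posterior probabilities of the omega2 class on the foreground
#'
#' Naive empirical Bayes (NEB) at the alternative MLEs: posterior of the
#' selected class at each site is `p2 L2 / ((1-p2) L1 + p2 L2)`. Optionally,
#' a grid empirical-Bayes variant averages the NEB posteriors over a 10 x 10
#' uniform grid on (p2, omega2 in [1, omega2_max]) weighted by the data
#' likelihood. Sites with posterior above the threshold are flagged.
#'
#' @param fit A converged `branch_site_fit`.
#' @param method `"neb"` (default) or `"grid"`.
#' @param threshold Flagging threshold (default 0.95).
#' @return data.frame with `site`, `posterior`, `flagged`.
#' @export
site_posteriors <- function(fit, method = c("neb", "grid"), threshold = 0.95) {
  method <- match.arg(method)
  if (!fit$converged) stop("fit did not converge; refusing to compute posteriors")
  comp_lik <- function(om1, p2, om2) {
    tree_loglik(fit$alignment, fit$tree, fit$kappa, fit$pi,
                components = list(
                  list(weight = 1 - p2, omega = om1, omega_fg = om1),
                  list(weight = p2, omega = om1, omega_fg = om2)),
                fg_edge = fit$fg_edge)
  }
  post_at <- function(p2, om2) {
    res <- comp_lik(fit$mle[["omega1"]], p2, om2)
    l1 <- res$comp_site_loglik[1, ]
    l2 <- res$comp_site_loglik[2, ]
    mx <- pmax(l1, l2)
    num <- p2 * exp(l2 - mx)
    list(post = num / ((1 - p2) * exp(l1 - mx) + num), loglik = res$loglik)
  }
  if (method == "neb") {
    post <- post_at(fit$mle[["p2"]], fit$mle[["omega2"]])$post
  } else {
    g <- 10L
    p2_grid <- (seq_len(g) - 0.5) / g
    om2_grid <- 1 + (fit$omega2_max - 1) * (seq_len(g) - 0.5) / g
    posts <- list(); lls <- numeric(0)
    for (a in p2_grid) for (b in om2_grid) {
      r <- post_at(a, b)
      posts[[length(posts) + 1L]] <- r$post
      lls <- c(lls, r$loglik)
    }
    wt <- exp(lls - max(lls))
    wt <- wt / sum(wt)
    post <- Reduce(`+`, Map(`*`, posts, wt))
  }
  data.frame(site = seq_along(post), posterior = post, flagged = post > threshold)
}

#' Branch-site selection scan over a batch of gene sets
#'
#' For every gene set (codon alignment + rooted tree), every branch is tested
#' with the branch-site LRT (fast path: branch lengths, kappa and omega1
#' anchored by the gene-wide single-omega fit). Raw chi-bar p-values are
#' Holm-adjusted within each set and Benjamini-Hochberg q-values are computed
#' across all tests of all sets.
#'
#' @param gene_sets Named list; each element is `list(alignment = codon
#'   matrix, tree = phylo)`.
#' @param null Null distribution passed to [lrt_pvalue()].
#' @param flag_sites Compute flagged-site counts (NEB > 0.95) for tests with
#'   `p_holm < 0.05` (default TRUE).
#' @return data.frame with columns `set`, `branch` (edge index), `branch_to`
#'   (child label), `omega1`, `p2_pct`, `omega2`, `LR`, `p_raw`, `p_holm`,
#'   `q_bh`, `n_flagged_sites`; sets failing validation are skipped with a
#'   warning.
#' @export
scan_gene_sets <- function(gene_sets, null = "chibar", flag_sites = TRUE) {
  if (is.null(names(gene_sets))) names(gene_sets) <- sprintf("set%03d", seq_along(gene_sets))
  rows <- list()
  fits <- list()
  for (nm in names(gene_sets)) {
    gs <- gene_sets[[nm]]
    ok <- tryCatch({
      stopifnot(setequal(rownames(gs$alignment), gs$tree$tip.label))
      TRUE
    }, error = function(e) {
      warning("skipping set ", nm, ": ", conditionMessage(e))
      FALSE
    })
    if (!ok) next
    anchor <- fit_single_omega(gs$alignment, gs$tree)
    om1 <- min(anchor$omega, 1)
    mu1 <- mixture_flux(anchor$kappa, om1, 1, anchor$pi)
    states <- matrix(codon_index(gs$alignment), nrow(gs$alignment),
                     ncol(gs$alignment), dimnames = dimnames(gs$alignment))
    pat <- compress_patterns(states)
    eig_bg <- mg94_eigen(build_mg94(anchor$kappa, om1, anchor$pi, flux = mu1))
    cache <- build_edge_caches(anchor$tree, pat$states, eig_bg, anchor$pi)
    nE <- nrow(gs$tree$edge)
    p_raw <- numeric(nE)
    for (ei in seq_len(nE)) {
      f <- fit_branch_site(gs$alignment, gs$tree, ei, anchor = anchor,
                           optimize_background = FALSE, cache = cache)
      fits[[paste(nm, ei)]] <- f
      p_raw[ei] <- lrt_pvalue(f$LR, null = null)
    }
    p_holm <- holm_bonferroni(p_raw)
    child <- gs$tree$edge[, 2]
    lab <- ifelse(child <= ape::Ntip(gs$tree), gs$tree$tip.label[child],
                  paste0("node", child))
    for (ei in seq_len(nE)) {
      f <- fits[[paste(nm, ei)]]
      rows[[length(rows) + 1L]] <- data.frame(
        set = nm, branch = ei, branch_to = lab[ei],
        omega1 = f$mle[["omega1"]], p2_pct = 100 * f$mle[["p2"]],
        omega2 = f$mle[["omega2"]], LR = f$LR, p_raw = p_raw[ei],
        p_holm = p_holm[ei], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$q_bh <- benjamini_hochberg(out$p_holm)
  out$n_flagged_sites <- NA_integer_
  if (flag_sites) {
    for (i in which(out$p_holm < 0.05)) {
      f <- fits[[paste(out$set[i], out$branch[i])]]
      if (f$converged) {
        out$n_flagged_sites[i] <- sum(site_posteriors(f)$flagged)
      }
    }
  }
  out <- out[order(out$set, out$branch), ]
  rownames(out) <- NULL
  out
}
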