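# Branch-site LRT machinery, multiple-testing wrappers and site posteriors

test_that("chi-bar p-values follow the boundary-mixture convention", {
  expect_equal(lrt_pvalue(0), 1)
  expect_equal(lrt_pvalue(2.71), 0.5 * stats::pchisq(2.71, 1, lower.tail = FALSE))
  expect_equal(lrt_pvalue(2.71), 0.0499, tolerance = 1e-3)
  lrs <- c(0, 0.5, 1, 2, 4, 8)
  expect_true(all(diff(lrt_pvalue(lrs)) < 0))
  expect_gt(lrt_pvalue(3, null = "chisq"), lrt_pvalue(3, null = "chibar"))
  expect_error(lrt_pvalue(-1), "negative")
})

test_that("Holm and BH wrappers match step-down/step-up enumeration", {
  expect_equal(holm_bonferroni(0.03), 0.03)
  expect_equal(holm_bonferroni(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(benjamini_hochberg(rep(0.2, 5)), rep(0.2, 5))
  set.seed(2)
  for (i in 1:5) {
    p <- stats::runif(7)
    # direct step-down oracle
    o <- order(p)
    m <- length(p)
    adj <- pmin(1, (m - seq_len(m) + 1) * p[o])
    adj <- cummax(adj)
    want <- numeric(m); want[o] <- adj
    expect_equal(holm_bonferroni(p), want)
    expect_true(all(benjamini_hochberg(p) >= p - 1e-12))
  }
})

test_that("the branch-site fit is nested and near-null on uniform-omega data", {
  tr <- melanogaster_group_tree()
  sim <- sim_codon_alignment(tr, 300, kappa = 2,
                             site_classes = data.frame(prop = 1, omega = 0.2),
                             seed = 51)
  anchor <- fit_single_omega(sim$alignment, tr)
  expect_equal(anchor$omega, 0.2, tolerance = 0.05)
  f <- fit_branch_site(sim$alignment, tr, fg_edge = 3, anchor = anchor,
                       optimize_background = FALSE)
  expect_gte(f$lnL_alt, f$lnL_null - 1e-6)
  expect_gte(f$LR, 0)
  expect_lt(f$LR, 6)  # no genuine signal simulated
  expect_error(fit_branch_site(sim$alignment, tr, fg_edge = 99, anchor = anchor),
               "does not exist")
})

test_that("simulated episodic selection is detected and parameters recovered", {
  tr <- melanogaster_group_tree()
  fg <- 3  # the 0.10-long internal edge above the suzukii-takahashii clade
  lr <- numeric(4); om2 <- numeric(4); p2 <- numeric(4)
  for (r in 1:4) {
    sim <- sim_codon_alignment(
      tr, 500, kappa = 2,
      site_classes = data.frame(prop = c(0.9, 0.1), omega = c(0.2, 0.2),
                                omega_fg = c(0.2, 5)),
      fg_edges = fg, seed = 700 + r)
    anchor <- fit_single_omega(sim$alignment, tr)
    f <- fit_branch_site(sim$alignment, tr, fg_edge = fg, anchor = anchor,
                         optimize_background = FALSE)
    lr[r] <- f$LR; om2[r] <- f$mle[["omega2"]]; p2[r] <- f$mle[["p2"]]
  }
  expect_gte(mean(om2 > 1), 0.75)
  expect_gte(mean(lrt_pvalue(lr) < 0.05), 0.5)
  # medians in the right neighbourhood of the simulated truth
  expect_lt(abs(stats::median(p2) - 0.1), 0.08)
})

test_that("site posteriors identify selected sites and stay calibrated", {
  tr <- melanogaster_group_tree()
  fg <- 3
  sim <- sim_codon_alignment(
    tr, 400, kappa = 2,
    site_classes = data.frame(prop = c(0.8, 0.2), omega = c(0.15, 0.15),
                              omega_fg = c(0.15, 8)),
    fg_edges = fg, seed = 61)
  anchor <- fit_single_omega(sim$alignment, tr)
  f <- fit_branch_site(sim$alignment, tr, fg_edge = fg, anchor = anchor,
                       optimize_background = FALSE)
  sp <- site_posteriors(f)
  expect_true(all(sp$posterior >= 0 & sp$posterior <= 1))
  truth <- sim$site_class == 2
  # flagged sites enriched in the truly selected class
  expect_gt(mean(sp$posterior[truth]), mean(sp$posterior[!truth]))
  if (any(sp$flagged)) {
    expect_gt(mean(truth[sp$flagged]), mean(truth))
  }
  # grid-EB variant agrees in ranking
  spg <- site_posteriors(f, method = "grid")
  expect_gt(stats::cor(sp$posterior, spg$posterior, method = "spearman"), 0.8)

  # null data: few false flags
  sim0 <- sim_codon_alignment(tr, 400, kappa = 2,
                              site_classes = data.frame(prop = 1, omega = 0.2),
                              seed = 62)
  a0 <- fit_single_omega(sim0$alignment, tr)
  f0 <- fit_branch_site(sim0$alignment, tr, fg_edge = fg, anchor = a0,
                        optimize_background = FALSE)
  sp0 <- site_posteriors(f0)
  expect_lte(mean(sp0$flagged), 0.05)
})

test_that("scan_gene_sets orders, corrects and is deterministic", {
  tr <- melanogaster_group_tree()
  sets <- list()
  for (i in 1:3) {
    fgsim <- if (i == 2) 3 else integer(0)
    cls <- if (i == 2) {
      data.frame(prop = c(0.9, 0.1), omega = c(0.2, 0.2), omega_fg = c(0.2, 8))
    } else {
      data.frame(prop = 1, omega = 0.2)
    }
    sim <- sim_codon_alignment(tr, 240, kappa = 2, site_classes = cls,
                               fg_edges = fgsim, seed = 900 + i)
    sets[[sprintf("fam%02d", i)]] <- list(alignment = sim$alignment, tree = tr)
  }
  res <- scan_gene_sets(sets, flag_sites = FALSE)
  expect_equal(sort(unique(res$set)), c("fam01", "fam02", "fam03"))
  expect_true(all(res$p_holm >= res$p_raw - 1e-12))
  expect_true(all(res$q_bh >= 0 & res$q_bh <= 1))
  # shuffled set order gives the identical sorted table
  res2 <- scan_gene_sets(sets[c(3, 1, 2)], flag_sites = FALSE)
  expect_equal(res[order(res$set, res$branch), c("set", "branch", "LR")],
               res2[order(res2$set, res2$branch), c("set", "branch", "LR")])
})
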