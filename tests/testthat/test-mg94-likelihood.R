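# MG94xHKY generator, F3x4 frequencies and the pruning likelihood engine

test_that("F3x4 frequencies are uniform for uniform composition", {
  # an alignment containing every sense codon once: positionwise nucleotide
  # composition of the full 64-codon table is uniform, but removing stops
  # biases it; construct an explicitly uniform case instead
  aln <- matrix(c("ACA", "CAC", "GTG", "TGT"), nrow = 1)
  f <- f3x4_frequencies(aln)
  expect_equal(sum(f), 1)
  expect_equal(length(f), 61L)
  # each position uniform over ACGT -> pi proportional to 1/64, renormalised
  expect_equal(unname(f), rep(1 / 61, 61), tolerance = 1e-12)
  # single repeated codon dominates
  f2 <- suppressWarnings(f3x4_frequencies(matrix("ATG", 2, 5)))
  expect_equal(names(which.max(f2)), "ATG")
})

test_that("the generator satisfies its structural contracts", {
  pi <- rep(1 / 61, 61)
  m <- build_mg94(2.5, 0.4, pi)
  expect_lt(max(abs(rowSums(m$Q))), 1e-10)
  expect_equal(-sum(pi * diag(m$Q)), 1, tolerance = 1e-12)     # unit flux
  # detailed balance
  expect_lt(max(abs(pi * m$Q - t(pi * t(m$Q)))), 1e-12)
  # no multi-nucleotide changes
  multi <- !chemevolve:::.codon_env$single
  diag(multi) <- FALSE
  expect_true(all(m$Q[multi] == 0))
  expect_error(build_mg94(-1, 1, pi), "kappa")
  expect_error(build_mg94(2, 1, rep(1 / 60, 61)), "sum")
})

test_that("P(t) from the eigendecomposition matches series summation", {
  pi <- f3x4_frequencies(matrix(sample(sense_codons(), 200, TRUE,
                                       prob = c(rep(2, 30), rep(1, 31))), 4, 50))
  m <- build_mg94(2, 0.3, pi)
  e <- mg94_eigen(m)
  for (t in c(0.01, 0.1, 1)) {
    P <- transition_probs(e, t)
    expect_equal(rowSums(P), rep(1, 61), tolerance = 1e-9)
    expect_lt(max(abs(P - oracle_expm(m$Q, t))), 1e-8)
  }
  expect_equal(transition_probs(e, 0), diag(61), tolerance = 1e-9)
})

test_that("pruning equals exhaustive state enumeration (<= 4 taxa, <= 5 sites)", {
  set.seed(14)
  fixtures <- list(
    list(tree = parse_newick("(a:0.1,b:0.3);"), nsite = 5),
    list(tree = parse_newick("((a:0.2,b:0.1):0.15,c:0.3);"), nsite = 5),
    list(tree = parse_newick("((a:0.2,b:0.1):0.1,(c:0.25,d:0.05):0.2);"),
         nsite = 2))
  for (fx in fixtures) {
    tr <- fx$tree
    sim <- sim_codon_alignment(tr, fx$nsite, kappa = 2,
                               site_classes = data.frame(prop = 1, omega = 0.5),
                               seed = 31)
    pi <- rep(1 / 61, 61)
    got <- tree_loglik(sim$alignment, tr, kappa = 2, pi = pi,
                       components = list(list(weight = 1, omega = 0.5)))
    eig <- mg94_eigen(build_mg94(2, 0.5, pi))
    P_list <- lapply(seq_len(nrow(tr$edge)),
                     function(ei) transition_probs(eig, tr$edge.length[ei]))
    states <- matrix(codon_index(sim$alignment), nrow(sim$alignment),
                     ncol(sim$alignment), dimnames = dimnames(sim$alignment))
    want <- oracle_tree_lik(tr, states, P_list, pi)
    expect_equal(got$loglik, want, tolerance = 1e-10)
  }
})

test_that("degenerate likelihood cases are exact", {
  # single-site likelihoods over all observations sum to 1 (2 and 3 taxa)
  pi <- rep(1 / 61, 61)
  for (nw in c("(a:0.2,b:0.4);", "((a:0.2,b:0.1):0.3,c:0.2);")) {
    tr <- parse_newick(nw)
    ntip <- ape::Ntip(tr)
    # full sum over all 61^ntip observations as one wide alignment
    full <- as.matrix(expand.grid(rep(list(1:61), ntip)))
    states <- t(full)
    rownames(states) <- tr$tip.label
    res <- tree_loglik(matrix(sense_codons()[states], nrow = ntip,
                              dimnames = list(tr$tip.label, NULL)),
                       tr, kappa = 2, pi = pi,
                       components = list(list(weight = 1, omega = 0.7)))
    expect_equal(sum(exp(res$site_loglik)), 1, tolerance = 1e-8)
  }

  # zero-length star: every row identical to root; lnL = sum log pi
  tr0 <- parse_newick("(a:0,b:0,c:0);")
  tr0 <- ape::multi2di(tr0)
  tr0$edge.length[] <- 0
  aln0 <- matrix(rep(c("ATG", "AAA"), each = 3), 3, 2,
                 dimnames = list(c("a", "b", "c"), NULL))
  res0 <- tree_loglik(aln0, tr0, kappa = 2, pi = rep(1 / 61, 61))
  expect_equal(res0$loglik, 2 * log(1 / 61), tolerance = 1e-9)

  # duplicated site pattern doubles its contribution
  tr <- parse_newick("((a:0.2,b:0.1):0.3,c:0.2);")
  one <- matrix(c("ATG", "AAA", "TGC"), 3, 1,
                dimnames = list(c("a", "b", "c"), NULL))
  two <- cbind(one, one)
  r1 <- tree_loglik(one, tr, 2, pi = rep(1 / 61, 61))
  r2 <- tree_loglik(two, tr, 2, pi = rep(1 / 61, 61))
  expect_equal(r2$loglik, 2 * r1$loglik, tolerance = 1e-10)

  expect_error(tree_loglik(one, parse_newick("((x:1,y:1):1,z:1);"), 2),
               "mismatch")
})
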