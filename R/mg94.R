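# MG94xHKY codon substitution model: generator construction, F3x4
# frequencies, and transition probabilities via symmetrized
# eigendecomposition (the generator is reversible, so sqrt(pi) similarity
# scaling yields a symmetric matrix with stable eigenvectors).

#' F3x4 codon frequencies from a codon alignment
#'
#' Position-specific nucleotide frequencies are estimated over all sequences
#' and sites, multiplied per codon, stop codons removed, and the result
#' renormalised over the 61 sense codons. A position with a zero-frequency
#' nucleotide receives a pseudocount of 1 with a warning.
#'
#' @param alignment Codon matrix: character matrix of 3-letter codons, rows =
#'   sequences, columns = codon sites.
#' @return Numeric vector of 61 frequencies (order [sense_codons()]), sum 1.
#' @export
f3x4_frequencies <- function(alignment) {
  if (length(alignment) == 0L) stop("empty alignment")
  cods <- as.vector(alignment)
  cods <- cods[grepl("^[ACGT]{3}$", cods)]
  if (length(cods) == 0L) stop("no valid codons in alignment")
  freq <- matrix(0, 3, 4, dimnames = list(NULL, NUCS))
  for (p in 1:3) {
    tab <- table(factor(substr(cods, p, p), levels = NUCS))
    if (any(tab == 0)) {
      warning("zero-frequency nucleotide at codon position ", p, "; pseudocount applied")
      tab <- tab + 1
    }
    freq[p, ] <- tab / sum(tab)
  }
  codons <- sense_codons()
  pi <- vapply(codons, function(cd) {
    freq[1, substr(cd, 1, 1)] * freq[2, substr(cd, 2, 2)] * freq[3, substr(cd, 3, 3)]
  }, numeric(1))
  pi <- pi / sum(pi)
  stats::setNames(pi, codons)
}

#' Build an MG94xHKY codon model
#'
#' Off-diagonal rates for single-nucleotide changes:
#' `q_ij = (kappa if transition else 1) * pi_j * (omega if nonsynonymous
#' else 1)`; codon pairs differing at more than one position have rate 0.
#' The generator is normalised so the expected flux
#' `sum_i pi_i sum_{j != i} q_ij` equals 1 substitution per codon per unit
#' time.
#'
#' Within a site-class mixture all classes must share one normalisation so
#' that high-omega classes evolve proportionally faster (the episodic
#' acceleration the branch-site test detects): pass the mixture flux from
#' [mixture_flux()] as `flux`. With the default (`flux = NULL`) the
#' generator is normalised by its own flux.
#'
#' @param kappa Transition/transversion ratio (> 0).
#' @param omega Nonsynonymous/synonymous ratio (>= 0).
#' @param pi Codon frequencies (61, order [sense_codons()], sum 1).
#' @param flux Optional shared normalisation constant (raw expected flux of
#'   the reference mixture; see [mixture_flux()]).
#' @return List of class `codon_model`: `Q`, `pi`, `kappa`, `omega`.
#' @export
build_mg94 <- function(kappa, omega, pi, flux = NULL) {
  if (kappa <= 0) stop("kappa must be > 0")
  if (omega < 0) stop("omega must be >= 0")
  if (length(pi) != 61L || abs(sum(pi) - 1) > 1e-8 || any(pi < 0))
    stop("pi must be 61 non-negative frequencies summing to 1")
  pi <- unname(pi)
  single <- .codon_env$single
  ts <- .codon_env$ts
  syn <- .codon_env$syn
  R <- matrix(0, 61, 61)
  R[single] <- 1
  R[single & ts] <- kappa
  R[single & !syn] <- R[single & !syn] * omega
  Q <- R * rep(pi, each = 61)  # q_ij ~ rate_factor * pi_j
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- if (is.null(flux)) -sum(pi * diag(Q)) else flux
  if (mu <= 0) stop("degenerate generator (all rates zero)")
  Q <- Q / mu
  structure(list(Q = Q, pi = pi, kappa = kappa, omega = omega),
            class = "codon_model")
}

#' Raw expected flux of an MG94 site-class mixture
#'
#' The weighted mean, over site classes, of the unnormalised expected
#' substitution rate `sum_i pi_i sum_{j != i} q_ij`. Dividing every class
#' generator by this constant puts branch lengths on the scale of expected
#' substitutions per codon site under the (background) mixture while
#' preserving the rate differences between classes.
#'
#' @param kappa Transition/transversion ratio.
#' @param omegas Per-class omega values.
#' @param weights Per-class proportions (sum 1).
#' @param pi Codon frequencies (61).
#' @return Positive scalar.
#' @export
mixture_flux <- function(kappa, omegas, weights, pi) {
  stopifnot(length(omegas) == length(weights), abs(sum(weights) - 1) < 1e-8)
  raw <- vapply(omegas, function(om) {
    single <- .codon_env$single
    ts <- .codon_env$ts
    syn <- .codon_env$syn
    R <- matrix(0, 61, 61)
    R[single] <- 1
    R[single & ts] <- kappa
    R[single & !syn] <- R[single & !syn] * om
    Q <- R * rep(pi, each = 61)
    sum(pi * rowSums(Q))
  }, numeric(1))
  sum(weights * raw)
}

#' Eigendecomposition of a reversible codon generator
#'
#' @param model A `codon_model`.
#' @return List with `values`, and matrices `right`, `left` such that
#'   `P(t) = right %*% diag(exp(values * t)) %*% left`.
#' @export
mg94_eigen <- function(model) {
  sq <- sqrt(model$pi)
  S <- model$Q * (sq / rep(sq, each = length(sq)))  # diag(sq) Q diag(1/sq): S_ij = sq_i q_ij / sq_j
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  right <- e$vectors / sq        # diag(1/sq) V
  left <- t(e$vectors * sq)      # t(V) diag(sq)
  list(values = e$values, right = right, left = left)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param eig Result of [mg94_eigen()].
#' @param t Branch length (>= 0), expected substitutions per codon site.
#' @return 61 x 61 stochastic matrix.
#' @export
transition_probs <- function(eig, t) {
  if (t < 0) stop("branch length must be >= 0")
  P <- eig$right %*% (exp(eig$values * t) * eig$left)
  # clamp tiny negative round-off
  P[P < 0] <- 0
  P
}
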