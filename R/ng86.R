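# Nei-Gojobori (1986) counting estimator of synonymous and nonsynonymous
# substitution rates, with the classic SNAP conventions: mutations to stop
# codons are excluded from the site denominators, evolutionary pathways
# passing through stop codons are discarded, and remaining pathways are
# weighted uniformly.

#' Synonymous and nonsynonymous site counts of one codon
#'
#' For each of the three codon positions the synonymous fraction among the
#' single-nucleotide neighbours is computed; neighbours that are stop codons
#' are removed from the denominator. The counts satisfy `s + n == 3` exactly.
#'
#' @param codon A single sense codon (3 letters, ACGT).
#' @return Named numeric vector `c(s = , n = )`.
#' @export
ng86_codon_sites <- function(codon) {
  codon <- toupper(codon)
  if (nchar(codon) != 3L) stop("codon must have 3 letters")
  if (is_stop_codon(codon)) stop("stop codon has no NG86 site counts: ", codon)
  aa0 <- codon_aa(codon)
  s <- 0
  for (pos in 1:3) {
    base <- substr(codon, pos, pos)
    if (!base %in% NUCS) stop("invalid nucleotide '", base, "' in codon ", codon)
    nb <- vapply(setdiff(NUCS, base), function(x) {
      out <- codon
      substr(out, pos, pos) <- x
      out
    }, character(1))
    nb <- nb[!is_stop_codon(nb)]
    if (length(nb) > 0L) {
      s <- s + sum(codon_aa(nb) == aa0) / length(nb)
    }
  }
  c(s = s, n = 3 - s)
}

#' Pathway-averaged synonymous/nonsynonymous differences between two codons
#'
#' Codons differing at d positions are connected by up to d! mutational
#' pathways of single-nucleotide steps. Pathways passing through a stop codon
#' are discarded; synonymous and nonsynonymous step counts are averaged
#' uniformly over the remaining pathways.
#'
#' @param a,b Sense codons.
#' @return Named numeric vector `c(sd = , nd = )`; `sd + nd` equals the number
#'   of differing positions.
#' @export
ng86_codon_differences <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (is_stop_codon(a) || is_stop_codon(b)) stop("stop codons not allowed")
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  d <- length(pos)
  if (d == 0L) return(c(sd = 0, nd = 0))
  perms <- permutations_of(pos)
  sd_tot <- 0; nd_tot <- 0; n_valid <- 0L
  for (k in seq_len(nrow(perms))) {
    cur <- a
    sd <- 0L; nd <- 0L; ok <- TRUE
    for (p in perms[k, ]) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (is_stop_codon(nxt)) { ok <- FALSE; break }
      if (codon_aa(cur) == codon_aa(nxt)) sd <- sd + 1L else nd <- nd + 1L
      cur <- nxt
    }
    if (ok) {
      sd_tot <- sd_tot + sd; nd_tot <- nd_tot + nd; n_valid <- n_valid + 1L
    }
  }
  if (n_valid == 0L) stop("no stop-free pathway between ", a, " and ", b)
  c(sd = sd_tot / n_valid, nd = nd_tot / n_valid)
}

# All permutations of a small vector (d <= 3 here).
permutations_of <- function(x) {
  n <- length(x)
  if (n == 1L) return(matrix(x, 1L, 1L))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- permutations_of(x[-i])
    out <- rbind(out, cbind(x[i], rest))
  }
  out
}

#' NG86 pairwise substitution estimates for a codon-aligned sequence pair
#'
#' Columns containing gaps or non-ACGT characters are skipped. Site counts S
#' and N are averaged over the two sequences; differences are pathway
#' averaged. Proportions are Jukes-Cantor corrected:
#' `dS = -(3/4) log(1 - (4/3) pS)` and likewise `dN`. Saturated proportions
#' (p >= 3/4) yield an undefined (NA) rate with `saturated = TRUE`.
#'
#' @param cds_a,cds_b Aligned DNA strings of equal length (multiple of 3).
#' @return A list of class `ng86_pair` with fields `S, N, Sd, Nd, pS, pN,
#'   dS, dN, ratio, n_codons, saturated`.
#' @export
ng86_pair <- function(cds_a, cds_b) {
  if (nchar(cds_a) != nchar(cds_b)) stop("aligned sequences must have equal length")
  ca <- split_codons(cds_a)
  cb <- split_codons(cds_b)
  usable <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb) &
    !is_stop_codon(ca) & !is_stop_codon(cb)
  ca <- ca[usable]; cb <- cb[usable]
  if (length(ca) == 0L) stop("no comparable (gap- and stop-free) codon columns")

  sites_a <- vapply(ca, ng86_codon_sites, numeric(2))
  sites_b <- vapply(cb, ng86_codon_sites, numeric(2))
  S <- (sum(sites_a["s", ]) + sum(sites_b["s", ])) / 2
  N <- (sum(sites_a["n", ]) + sum(sites_b["n", ])) / 2

  diffs <- mapply(ng86_codon_differences, ca, cb)
  Sd <- sum(diffs["sd", ]); Nd <- sum(diffs["nd", ])

  pS <- Sd / S; pN <- Nd / N
  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    if (p == 0) return(0)
    -0.75 * log(1 - 4 * p / 3)
  }
  dS <- jc(pS); dN <- jc(pN)
  saturated <- pS >= 0.75 || pN >= 0.75
  ratio <- if (saturated || is.na(dS) || dS == 0) NA_real_ else dN / dS
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 dS = dS, dN = dN, ratio = ratio,
                 n_codons = length(ca), saturated = saturated),
            class = "ng86_pair")
}

#' @export
print.ng86_pair <- function(x, ...) {
  cat(sprintf("NG86 pairwise substitution estimates (%d codons)\n", x$n_codons))
  cat(sprintf("  S = %.3f  N = %.3f  Sd = %.3f  Nd = %.3f\n", x$S, x$N, x$Sd, x$Nd))
  cat(sprintf("  pS = %.5f  pN = %.5f  dS = %.5f  dN = %.5f\n", x$pS, x$pN, x$dS, x$dN))
  if (x$saturated) cat("  saturated: Jukes-Cantor correction undefined\n")
  cat(sprintf("  dN/dS = %s\n", ifelse(is.na(x$ratio), "undefined", sprintf("%.4f", x$ratio))))
  invisible(x)
}
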