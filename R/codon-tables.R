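# Shared codon-level machinery: the 61 sense codons of the standard genetic
# code, their amino-acid translations, and the single-nucleotide neighbour
# structure used by both the NG86 counting estimator and the MG94xHKY
# likelihood engine.

NUCS <- c("A", "C", "G", "T")

#' The 61 sense codons of the standard genetic code
#'
#' Codons are ordered lexicographically (A < C < G < T) with the three stop
#' codons (TAA, TAG, TGA) removed. This ordering is the state order used by
#' all codon-model matrices in the package.
#'
#' @return Character vector of length 61.
#' @export
sense_codons <- function() {
  .codon_env$codons
}

#' Translate a single codon to its amino acid
#'
#' @param codon Character vector of 3-letter codons (ACGT alphabet).
#' @return Character vector of one-letter amino-acid codes, `"*"` for stops.
#' @export
codon_aa <- function(codon) {
  aa <- unname(Biostrings::GENETIC_CODE[codon])
  if (anyNA(aa)) stop("invalid codon(s): ", paste(codon[is.na(aa)], collapse = ", "))
  aa
}

is_stop_codon <- function(codon) {
  codon %in% c("TAA", "TAG", "TGA")
}

# transition = purine<->purine or pyrimidine<->pyrimidine
is_transition_pair <- function(a, b) {
  (a %in% c("A", "G") & b %in% c("A", "G")) | (a %in% c("C", "T") & b %in% c("C", "T"))
}

# Package-local cache built at load time.
.codon_env <- new.env(parent = emptyenv())

build_codon_tables <- function() {
  all64 <- apply(expand.grid(NUCS, NUCS, NUCS, stringsAsFactors = FALSE)[, 3:1],
                 1, paste0, collapse = "")
  all64 <- sort(all64)
  codons <- all64[!is_stop_codon(all64)]
  stopifnot(length(codons) == 61L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])

  n <- length(codons)
  # Single-nucleotide-difference structure among sense codons
  diff_pos <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    ci <- strsplit(codons[i], "")[[1]]
    for (j in seq_len(n)) {
      cj <- strsplit(codons[j], "")[[1]]
      d <- which(ci != cj)
      diff_pos[i, j] <- if (length(d) == 1L) d else 0L
    }
  }
  single <- diff_pos > 0L
  ts <- matrix(FALSE, n, n)
  syn <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (single[i, j]) {
      p <- diff_pos[i, j]
      a <- substr(codons[i], p, p); b <- substr(codons[j], p, p)
      ts[i, j] <- is_transition_pair(a, b)
      syn[i, j] <- aa[i] == aa[j]
    }
  }
  assign("codons", codons, envir = .codon_env)
  assign("aa", aa, envir = .codon_env)
  assign("single", single, envir = .codon_env)
  assign("ts", ts, envir = .codon_env)
  assign("syn", syn, envir = .codon_env)
  assign("index", stats::setNames(seq_len(n), codons), envir = .codon_env)
  invisible(NULL)
}

codon_index <- function(codons) {
  idx <- .codon_env$index[codons]
  if (anyNA(idx)) {
    bad <- codons[is.na(idx)]
    stop("not a sense codon: ", paste(unique(bad), collapse = ", "))
  }
  unname(idx)
}

# Split a DNA string into codons; length must be divisible by 3.
split_codons <- function(dna) {
  dna <- toupper(dna)
  n <- nchar(dna)
  if (n %% 3L != 0L) stop("sequence length ", n, " is not divisible by 3")
  substring(dna, seq(1L, n, 3L), seq(3L, n, 3L))
}

.onLoad <- function(libname, pkgname) {
  build_codon_tables()
}
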