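#' Simulate a founder haplotype panel
#'
#' Generates binary founder haplotypes over a genetic map with tunable
#' local linkage disequilibrium.  Alleles along a chromosome follow a
#' first-order Markov chain: site j copies site j-1's allele state with
#' probability `ld_strength`, otherwise draws fresh from that site's base
#' frequency.  `ld_strength = 0` gives independent sites; values near 1
#' give long haplotype blocks.  Sites whose realised minor allele
#' frequency falls below `maf_floor` are redrawn (independently) a bounded
#' number of times.
#'
#' @param n_haplotypes Number of haplotypes (two per founder; must be even).
#' @param map Genetic map tibble from [genetic_map()].
#' @param ld_strength Adjacent-site copy probability in `[0, 1)`.
#' @param maf_floor Minimum minor allele frequency per site, in `(0, 0.5)`.
#' @param seed Integer seed; identical inputs give an identical panel.
#' @param max_attempts Redraw rounds for sites violating `maf_floor`.
#'
#' @return Integer 0/1 matrix, `n_haplotypes` rows by `nrow(map)` columns.
#' @export
simulate_founders <- function(n_haplotypes, map, ld_strength = 0.95,
                              maf_floor = 0.05, seed = NULL,
                              max_attempts = 20) {
  stopifnot(n_haplotypes >= 2, n_haplotypes %% 2 == 0,
            ld_strength >= 0, ld_strength < 1)
  if (maf_floor <= 0 || maf_floor >= 0.5) {
    stop("maf_floor must lie in (0, 0.5)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  M <- nrow(map)
  lo <- max(1.5 * maf_floor, 0.1)
  base_freq <- runif(M, lo, 1 - lo)
  H <- matrix(0L, n_haplotypes, M)
  for (ch in unique(map$chrom)) {
    cols <- which(map$chrom == ch)
    prev <- rbinom(n_haplotypes, 1, base_freq[cols[1]])
    H[, cols[1]] <- prev
    for (j in cols[-1]) {
      copy <- runif(n_haplotypes) < ld_strength
      fresh <- rbinom(n_haplotypes, 1, base_freq[j])
      prev <- ifelse(copy, prev, fresh)
      H[, j] <- prev
    }
  }
  for (attempt in seq_len(max_attempts)) {
    f <- colMeans(H)
    bad <- which(pmin(f, 1 - f) < maf_floor)
    if (length(bad) == 0) return(H)
    for (j in bad) H[, j] <- rbinom(n_haplotypes, 1, base_freq[j])
  }
  f <- colMeans(H)
  if (any(pmin(f, 1 - f) < maf_floor)) {
    stop("could not satisfy maf_floor = ", maf_floor, " after ",
         max_attempts, " redraw rounds", call. = FALSE)
  }
  H
}

#' Assign multi-allelic QTL alleles to founder haplotypes
#'
#' Labels every founder haplotype with one of `n_alleles` QTL alleles at a
#' map position.  The QTL is a separate (non-SNP) locus: its labels ride on
#' the founder haplotypes and are transmitted through [gene_drop()] with
#' recombination like any locus, so no single bi-allelic SNP can tag it
#' perfectly.
#'
#' @param n_haplotypes Number of founder haplotypes to label.
#' @param map Genetic map tibble.
#' @param chrom Chromosome carrying the QTL.
#' @param position QTL position in cM; must lie within the chromosome's
#'   mapped range.
#' @param n_alleles Number of QTL alleles (at least 3).
#' @param seed Optional integer seed.
#'
#' @return Integer vector of labels in `1:n_alleles`, one per haplotype;
#'   every allele is represented at least once.
#' @export
assign_multiallelic_qtl <- function(n_haplotypes, map, chrom, position,
                                    n_alleles = 3, seed = NULL) {
  if (n_alleles < 3) {
    stop("a multi-allelic QTL needs n_alleles >= 3", call. = FALSE)
  }
  pos <- map$pos_cM[map$chrom == chrom]
  if (length(pos) == 0 || position < min(pos) || position > max(pos)) {
    stop("QTL position ", position, " cM outside the mapped range of ",
         "chromosome ", chrom, call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (n_haplotypes < n_alleles) {
    stop("need at least one haplotype per allele", call. = FALSE)
  }
  for (i in seq_len(100)) {
    freq <- runif(n_alleles, 0.2, 1)
    labels <- sample.int(n_alleles, n_haplotypes, replace = TRUE,
                         prob = freq / sum(freq))
    if (length(unique(labels)) == n_alleles) return(labels)
  }
  # guarantee representation on pathological draws
  labels[seq_len(n_alleles)] <- seq_len(n_alleles)
  labels
}
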