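#' Simulate a complete pedigreed QTL mapping study
#'
#' End-to-end generator: builds the half-sib pedigree, simulates a founder
#' haplotype panel with local LD, assigns the multi-allelic QTL labels,
#' drops gametes through the pedigree with Haldane recombination, and
#' simulates phenotypes under the eight-QTL architecture of
#' [default_qtl_truth()].  The defaults reproduce the benchmark study
#' conditions: 2000 phenotyped and genotyped animals, 5 x 1998 SNPs at
#' 0.05 cM spacing.
#'
#' The two epistatic QTL are given positively associated founder alleles
#' (`epi_founder_ld`): founder haplotypes carrying the increasing allele at
#' the first member preferentially carry it at the second.  This emulates
#' the long-range LD a small, drifted founder population accumulates and is
#' what lets the first epistatic QTL absorb most of the pair's signal --
#' the masking behaviour the conditional scan probes (see the vignette).
#'
#' @param seed Integer seed driving every stochastic step.
#' @param n_sires,n_dams_per_sire,n_progeny_per_family,n_phenotyped_per_family
#'   Pedigree design, see [build_pedigree()].
#' @param map Genetic map, see [genetic_map()].
#' @param truth QTL truth table, see [default_qtl_truth()].
#' @param h2_polygenic Polygenic variance fraction.
#' @param ld_strength,maf_floor Founder panel parameters, see
#'   [simulate_founders()].
#' @param n_alleles_multi Allele count of the multi-allelic QTL.
#' @param epi_founder_ld Probability that a founder allele at the second
#'   epistatic member is copied from the first (0 = independent loci).
#' @param imprinting_parent Expressed parent for imprinted QTL.
#'
#' @return An object of class `pg_sim`: a list with `pedigree`, `map`,
#'   `haplos` (phased `mat`/`pat` matrices over all individuals),
#'   `qtl_labels` (multi-allelic labels or `NULL`), `phenotypes`, `truth`
#'   (with realised variance fractions), `variances` and `params`.
#' @export
#' @examples
#' sim <- simulate_qtlmas(seed = 1, n_sires = 2, n_dams_per_sire = 2,
#'                        n_progeny_per_family = 3,
#'                        n_phenotyped_per_family = 2,
#'                        map = genetic_map(2, 50, 1))
#' nrow(sim$phenotypes)
simulate_qtlmas <- function(seed,
                            n_sires = 20, n_dams_per_sire = 10,
                            n_progeny_per_family = 15,
                            n_phenotyped_per_family = 10,
                            map = genetic_map(),
                            truth = default_qtl_truth(),
                            h2_polygenic = 0.30,
                            ld_strength = 0.95, maf_floor = 0.05,
                            n_alleles_multi = 3,
                            epi_founder_ld = 0.6,
                            imprinting_parent = "paternal") {
  set.seed(seed)
  pedigree <- build_pedigree(n_sires, n_dams_per_sire,
                             n_progeny_per_family, n_phenotyped_per_family)
  n_founders <- sum(pedigree$sire == 0)
  founders <- simulate_founders(2 * n_founders, map,
                                ld_strength = ld_strength,
                                maf_floor = maf_floor)

  multi <- which(truth$architecture == "multiallelic")
  extra_pos <- NULL; extra_alleles <- NULL
  if (length(multi)) {
    k <- multi[1]
    labels <- assign_multiallelic_qtl(2 * n_founders, map,
                                      truth$chrom[k], truth$pos_cM[k],
                                      n_alleles = n_alleles_multi)
    extra_pos <- truth[k, c("chrom", "pos_cM")]
    extra_alleles <- matrix(labels, ncol = 1)
  }

  epi <- which(!is.na(truth$epi_fraction))
  if (length(epi) && epi_founder_ld > 0) {
    k1 <- epi[1]; k2 <- truth$partner[k1]
    j1 <- qtl_snp_index(map, truth$chrom[k1], truth$pos_cM[k1])
    j2 <- qtl_snp_index(map, truth$chrom[k2], truth$pos_cM[k2])
    copy <- runif(2 * n_founders) < epi_founder_ld
    founders[copy, j2] <- founders[copy, j1]
  }

  haplos <- gene_drop(pedigree, founders, map,
                      extra_pos = extra_pos, extra_alleles = extra_alleles)
  qtl_labels <- if (length(multi)) {
    list(mat = haplos$extra_mat[, 1], pat = haplos$extra_pat[, 1])
  }

  phe <- simulate_phenotypes(pedigree, map, haplos, truth,
                             qtl_labels = qtl_labels,
                             h2_polygenic = h2_polygenic,
                             imprinting_parent = imprinting_parent)

  structure(list(
    pedigree = pedigree, map = map,
    haplos = list(mat = haplos$mat, pat = haplos$pat),
    qtl_labels = qtl_labels,
    phenotypes = phe$phenotypes, truth = phe$truth,
    variances = phe$variances,
    params = list(seed = seed, h2_polygenic = h2_polygenic,
                  ld_strength = ld_strength, maf_floor = maf_floor,
                  epi_founder_ld = epi_founder_ld,
                  imprinting_parent = imprinting_parent)
  ), class = "pg_sim")
}

#' @export
print.pg_sim <- function(x, ...) {
  cat("Simulated pedigreed QTL study (seed ", x$params$seed, ")\n", sep = "")
  cat("  individuals:", nrow(x$pedigree),
      " phenotyped/genotyped:", nrow(x$phenotypes), "\n")
  cat("  SNPs:", nrow(x$map), "on", length(unique(x$map$chrom)),
      "chromosomes\n")
  cat("  QTL:", nrow(x$truth), "\n")
  invisible(x)
}

#' Phased genotypes of the genotyped (phenotyped) animals
#'
#' @param sim A `pg_sim` object.
#' @return List with `mat` and `pat` 0/1 matrices restricted to the
#'   phenotyped individuals, rownames = ids.
#' @export
phased_genotypes <- function(sim) {
  ids <- as.character(sim$phenotypes$id)
  list(mat = sim$haplos$mat[ids, , drop = FALSE],
       pat = sim$haplos$pat[ids, , drop = FALSE])
}

#' Allele dosage matrix (0/1/2) of the genotyped animals
#'
#' @param sim A `pg_sim` object.
#' @return Integer matrix, individuals x SNPs.
#' @export
dosage_matrix <- function(sim) {
  g <- phased_genotypes(sim)
  g$mat + g$pat
}
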