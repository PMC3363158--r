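#' Default eight-QTL truth table
#'
#' The simulated architecture mirrors the benchmark design this package
#' emulates: eight QTL on five chromosomes -- a multi-allelic QTL of
#' largest effect on chromosome 1, two linked additive QTL on chromosome 2,
#' two additive QTL on chromosome 3, an imprinted QTL on chromosome 4 and
#' an additive-by-additive epistatic pair on chromosome 5.  Positions are
#' fixed; the variance fractions are this generator's declared defaults
#' (the chromosome-1 QTL is anchored at 10.2% of phenotypic variance, the
#' others are plausible mid-sized effects; see the methods vignette).
#'
#' @return A tibble with columns `qtl` (index), `chrom`, `pos_cM`,
#'   `architecture`, `partner` (index of the other epistatic member),
#'   `target_fraction` (marginal variance fraction) and `epi_fraction`
#'   (variance fraction of the pair's interaction term, on the first
#'   member's row).
#' @export
default_qtl_truth <- function() {
  tibble::tibble(
    qtl = 1:8,
    chrom = c(1L, 2L, 2L, 3L, 3L, 4L, 5L, 5L),
    pos_cM = c(2.85, 81.90, 93.75, 5.00, 15.00, 32.20, 36.30, 99.20),
    architecture = c("multiallelic", "additive", "additive", "additive",
                     "additive", "imprinted", "epistatic_pair_member",
                     "epistatic_pair_member"),
    partner = c(NA, NA, NA, NA, NA, NA, 8L, 7L),
    target_fraction = c(0.102, 0.06, 0.04, 0.05, 0.03, 0.04, 0.03, 0.015),
    epi_fraction = c(NA, NA, NA, NA, NA, NA, 0.04, NA)
  )
}

qtl_snp_index <- function(map, chrom, pos_cM) {
  cand <- which(map$chrom == chrom)
  if (length(cand) == 0) stop("no SNPs on chromosome ", chrom, call. = FALSE)
  cand[which.min(abs(map$pos_cM[cand] - pos_cM))]
}

#' Simulate phenotypes from phased genotypes and a QTL truth table
#'
#' Builds phenotypes as `mean + sum(QTL terms) + polygenic + residual` on a
#' phenotypic-variance scale of 1:
#' * additive QTL contribute `a * dosage` at the SNP on the QTL position;
#' * the multi-allelic QTL contributes allele-specific additive values for
#'   the two carried QTL alleles;
#' * the imprinted QTL acts through the allele inherited from one parent
#'   only (`imprinting_parent`, paternal by default);
#' * the epistatic pair contributes its two small marginal terms plus an
#'   additive-by-additive interaction (product of centred dosages).
#'
#' Each term's raw coefficient is rescaled once against its realised sample
#' variance so the realised variance fraction tracks the target; realised
#' fractions are reported back on the truth table.  Polygenic values follow
#' the pedigree (parent average plus a Mendelian-sampling deviation).
#'
#' @param pedigree Pedigree tibble.
#' @param map Genetic map tibble.
#' @param haplos List with `mat`/`pat` phased SNP matrices from
#'   [gene_drop()] (all pedigree individuals).
#' @param truth QTL truth tibble, see [default_qtl_truth()].
#' @param qtl_labels Optional list with `mat`/`pat` integer label vectors
#'   for the multi-allelic QTL (one entry per individual); required when
#'   the truth contains a multi-allelic row.
#' @param h2_polygenic Polygenic variance fraction in `[0, 1)`.
#' @param seed Optional integer seed.
#' @param mean_value Phenotype grand mean.
#' @param imprinting_parent `"paternal"` or `"maternal"` expression for
#'   imprinted QTL.
#'
#' @return A list: `phenotypes` (tibble `id`, `value`, one row per
#'   phenotyped individual), `truth` (input truth with
#'   `realized_fraction` and `realized_epi_fraction` columns) and
#'   `variances` (named vector of the generating variance shares).
#' @export
simulate_phenotypes <- function(pedigree, map, haplos, truth,
                                qtl_labels = NULL, h2_polygenic = 0.30,
                                seed = NULL, mean_value = 0,
                                imprinting_parent = c("paternal",
                                                      "maternal")) {
  imprinting_parent <- match.arg(imprinting_parent)
  stopifnot(h2_polygenic >= 0, h2_polygenic < 1)
  budget <- sum(truth$target_fraction) +
    sum(truth$epi_fraction, na.rm = TRUE) + h2_polygenic
  if (budget >= 1) {
    stop("variance budget (QTL fractions + polygenic) reaches ",
         round(budget, 3), "; must stay below 1", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  phen_ids <- pedigree$id[pedigree$phenotyped]
  rows <- match(as.character(phen_ids), rownames(haplos$mat))
  n <- length(phen_ids)
  scale_to <- function(term, frac) {
    v <- var(term)
    if (v <= 0) return(rep(0, length(term)))
    term * sqrt(frac / v)
  }

  terms <- matrix(0, n, nrow(truth))
  epi_term <- rep(0, n)
  dosage_at <- function(k) {
    j <- qtl_snp_index(map, truth$chrom[k], truth$pos_cM[k])
    haplos$mat[rows, j] + haplos$pat[rows, j]
  }
  for (k in seq_len(nrow(truth))) {
    arch <- truth$architecture[k]
    if (arch == "additive" || arch == "epistatic_pair_member") {
      terms[, k] <- scale_to(dosage_at(k), truth$target_fraction[k])
    } else if (arch == "multiallelic") {
      if (is.null(qtl_labels)) {
        stop("truth contains a multi-allelic QTL but no qtl_labels given",
             call. = FALSE)
      }
      lm_ <- qtl_labels$mat[rows]; lp_ <- qtl_labels$pat[rows]
      vals <- rnorm(max(lm_, lp_))
      terms[, k] <- scale_to(vals[lm_] + vals[lp_],
                             truth$target_fraction[k])
    } else if (arch == "imprinted") {
      j <- qtl_snp_index(map, truth$chrom[k], truth$pos_cM[k])
      expressed <- if (imprinting_parent == "paternal") {
        haplos$pat[rows, j]
      } else {
        haplos$mat[rows, j]
      }
      terms[, k] <- scale_to(expressed, truth$target_fraction[k])
    } else {
      stop("unknown QTL architecture: ", arch, call. = FALSE)
    }
  }
  epi_rows <- which(!is.na(truth$epi_fraction))
  for (k in epi_rows) {
    x1 <- dosage_at(k); x2 <- dosage_at(truth$partner[k])
    inter <- (x1 - mean(x1)) * (x2 - mean(x2))
    epi_term <- epi_term + scale_to(inter, truth$epi_fraction[k])
  }

  # polygenic values down the pedigree: parent average + Mendelian sampling
  su2 <- h2_polygenic
  u <- numeric(nrow(pedigree))
  sp <- match(pedigree$sire, pedigree$id, nomatch = 0L)
  dp <- match(pedigree$dam, pedigree$id, nomatch = 0L)
  for (i in seq_len(nrow(pedigree))) {
    if (sp[i] == 0L && dp[i] == 0L) {
      u[i] <- rnorm(1, 0, sqrt(su2))
    } else {
      u[i] <- (u[sp[i]] + u[dp[i]]) / 2 + rnorm(1, 0, sqrt(su2 / 2))
    }
  }

  se2 <- 1 - budget
  e <- rnorm(n, 0, sqrt(se2))
  y <- mean_value + rowSums(terms) + epi_term +
    u[match(phen_ids, pedigree$id)] + e
  vy <- var(y)

  truth$realized_fraction <- vapply(seq_len(nrow(truth)),
                                    function(k) var(terms[, k]) / vy, 0)
  truth$realized_epi_fraction <- NA_real_
  if (length(epi_rows)) {
    truth$realized_epi_fraction[epi_rows[1]] <- var(epi_term) / vy
  }

  list(
    phenotypes = tibble::tibble(id = phen_ids, value = y),
    truth = truth,
    variances = c(polygenic = su2, residual = se2,
                  qtl = sum(truth$target_fraction),
                  epistatic = sum(truth$epi_fraction, na.rm = TRUE))
  )
}
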