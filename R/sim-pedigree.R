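#' Build a half-sib family pedigree
#'
#' Constructs the three-tier pedigree used throughout the package: unrelated
#' founder sires and dams, each sire mated to a fixed number of dams, each
#' mating producing a full-sib family of fixed size.  A fixed number of
#' progeny per full-sib family is flagged as phenotyped (and genotyped); the
#' defaults reproduce the 20-sire x 10-dam x 15-progeny design with 10
#' phenotyped progeny per family, i.e. 2000 phenotyped animals.
#'
#' Individuals are numbered so that parents always precede offspring: sires
#' first, then dams, then progeny family by family.
#'
#' @param n_sires Number of founder sires.
#' @param n_dams_per_sire Dams mated to each sire.
#' @param n_progeny_per_family Full-sib family size.
#' @param n_phenotyped_per_family Progeny per full-sib family carrying a
#'   phenotype record; must not exceed `n_progeny_per_family`.
#'
#' @return A tibble with one row per individual and columns `id`, `sire`,
#'   `dam` (0 for founders), `generation` (`"founder"` or `"progeny"`) and
#'   `phenotyped` (logical).
#' @export
#' @examples
#' ped <- build_pedigree(2, 3, 4, 2)
#' sum(ped$phenotyped)  # 2 * 3 * 2 = 12
build_pedigree <- function(n_sires = 20, n_dams_per_sire = 10,
                           n_progeny_per_family = 15,
                           n_phenotyped_per_family = 10) {
  counts <- c(n_sires, n_dams_per_sire, n_progeny_per_family,
              n_phenotyped_per_family)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("all pedigree counts must be positive integers", call. = FALSE)
  }
  if (n_phenotyped_per_family > n_progeny_per_family) {
    stop("n_phenotyped_per_family cannot exceed n_progeny_per_family",
         call. = FALSE)
  }

  n_dams  <- n_sires * n_dams_per_sire
  sires   <- tibble::tibble(id = seq_len(n_sires), sire = 0L, dam = 0L)
  dams    <- tibble::tibble(id = n_sires + seq_len(n_dams),
                            sire = 0L, dam = 0L)

  fam <- tidyr::expand_grid(
    s = seq_len(n_sires),
    d = seq_len(n_dams_per_sire),
    k = seq_len(n_progeny_per_family)
  )
  progeny <- tibble::tibble(
    id   = n_sires + n_dams + seq_len(nrow(fam)),
    sire = fam$s,
    dam  = n_sires + (fam$s - 1L) * n_dams_per_sire + fam$d,
    phenotyped = fam$k <= n_phenotyped_per_family
  )

  dplyr::bind_rows(
    dplyr::mutate(sires, generation = "founder", phenotyped = FALSE),
    dplyr::mutate(dams,  generation = "founder", phenotyped = FALSE),
    dplyr::mutate(progeny, generation = "progeny", .before = "phenotyped")
  )
}

#' Regular SNP map over equally spaced chromosomes
#'
#' @param n_chrom Number of chromosomes.
#' @param n_snp_per_chrom SNPs per chromosome.
#' @param spacing_cM Distance between adjacent SNPs in centimorgans; the
#'   first SNP of each chromosome sits at 0 cM.
#'
#' @return A tibble with columns `chrom`, `idx` (1-based index within the
#'   chromosome), `snp` (genome-wide marker name) and `pos_cM`.
#' @export
genetic_map <- function(n_chrom = 5, n_snp_per_chrom = 1998,
                        spacing_cM = 0.05) {
  stopifnot(n_chrom >= 1, n_snp_per_chrom >= 1, spacing_cM > 0)
  tidyr::expand_grid(chrom = seq_len(n_chrom),
                     idx = seq_len(n_snp_per_chrom)) |>
    dplyr::mutate(
      snp = sprintf("c%d_s%04d", .data$chrom, .data$idx),
      pos_cM = (.data$idx - 1L) * spacing_cM
    )
}

check_pedigree_order <- function(pedigree) {
  pos <- match(pedigree$id, pedigree$id)
  sire_pos <- match(pedigree$sire, pedigree$id)
  dam_pos  <- match(pedigree$dam, pedigree$id)
  bad <- (pedigree$sire != 0 & (is.na(sire_pos) | sire_pos >= pos)) |
         (pedigree$dam  != 0 & (is.na(dam_pos)  | dam_pos  >= pos))
  if (any(bad)) {
    stop("pedigree is not ordered parents-before-offspring (first bad id: ",
         pedigree$id[which(bad)[1]], ")", call. = FALSE)
  }
  invisible(pedigree)
}
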