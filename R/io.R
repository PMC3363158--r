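#' Write a simulated study to disk
#'
#' Emits the standard runtime files of the pipeline: a VCF 4.2 with phased
#' genotypes (`0|1` style) for the genotyped animals, and TSVs for the
#' pedigree, phenotypes, QTL truth and SNP map.  Positions are genetic
#' (cM); the VCF `POS` column carries `cM * 10^4` as an integer, which is
#' declared in the header.
#'
#' @param sim A `pg_sim` object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named vector of the file paths written.
#' @export
write_sim_data <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             pedigree = file.path(dir, "pedigree.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             truth = file.path(dir, "truth.tsv"),
             map = file.path(dir, "map.tsv"))

  readr::write_tsv(sim$pedigree, paths["pedigree"])
  readr::write_tsv(sim$phenotypes, paths["phenotypes"])
  readr::write_tsv(sim$truth, paths["truth"])
  readr::write_tsv(sim$map[, c("chrom", "snp", "pos_cM")], paths["map"])
  write_phased_vcf(phased_genotypes(sim), sim$map, paths["vcf"])
  invisible(paths)
}

#' Write phased genotypes as a VCF 4.2 file
#'
#' @param phased List with `mat`/`pat` 0/1 matrices (individuals x SNPs,
#'   rownames = ids).
#' @param map Genetic map tibble aligned to the matrix columns.
#' @param path Output file (plain text).
#' @export
write_phased_vcf <- function(phased, map, path) {
  ids <- rownames(phased$mat)
  gt <- matrix(paste0(t(phased$mat), "|", t(phased$pat)),
               nrow = nrow(map))  # SNPs x individuals
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=pedgwas",
    "##INFO=<ID=CM,Number=1,Type=Float,Description=\"Genetic position in cM; POS = cM*10^4\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype, maternal|paternal\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  )
  body <- paste(map$chrom, as.integer(round(map$pos_cM * 1e4)), map$snp,
                "A", "B", ".", "PASS", paste0("CM=", map$pos_cM), "GT",
                apply(gt, 1, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read phased genotypes from a VCF written by [write_phased_vcf()]
#'
#' Uses the `vcfR` parser; requires phased GT fields.
#'
#' @param path VCF file.
#' @return List with `mat`/`pat` 0/1 matrices and a `map` tibble
#'   (`chrom`, `snp`, `pos_cM` recovered from POS / 10^4).
#' @export
read_phased_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  if (any(!grepl("|", gt, fixed = TRUE))) {
    stop("VCF contains unphased genotypes", call. = FALSE)
  }
  halves <- strsplit(as.vector(gt), "|", fixed = TRUE)
  a1 <- matrix(as.integer(vapply(halves, `[`, "", 1L)), nrow = nrow(gt))
  a2 <- matrix(as.integer(vapply(halves, `[`, "", 2L)), nrow = nrow(gt))
  ids <- colnames(gt)
  mat <- t(a1); pat <- t(a2)
  rownames(mat) <- rownames(pat) <- ids
  map <- tibble::tibble(
    chrom = as.integer(vcfR::getCHROM(v)),
    snp = vcfR::getID(v),
    pos_cM = vcfR::getPOS(v) / 1e4
  )
  colnames(mat) <- colnames(pat) <- map$snp
  list(mat = mat, pat = pat, map = map)
}
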