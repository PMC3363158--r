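# direct dense evaluation of the restricted likelihood at given variances:
# -1/2 [ (n-p) log 2pi + log|V| + log|X'V^-1 X| + y'Py ]
brute_reml_ll <- function(y, X, V) {
  n <- length(y); p <- ncol(X)
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtVX) %*% t(X) %*% Vi
  as.numeric(-0.5 * ((n - p) * log(2 * pi) +
                       determinant(V)$modulus +
                       determinant(XtVX)$modulus +
                       drop(t(y) %*% P %*% y)))
}

# ---- cached calibration / recovery experiments (shared between the
# ---- module tests and the acceptance suite; each runs once per session)

# empirical type-I error of the SNP scan under a polygenic-only null:
# one genotype panel, fresh phenotypes per replicate
mma_type1_rate <- function(n_reps = 200) {
  cache_get("type1", {
    ped <- build_pedigree(10, 4, 5, 5)      # 200 phenotyped
    A <- additive_relationship(ped)
    ids <- as.character(ped$id[ped$phenotyped])
    map <- genetic_map(1, 200, 0.5)
    set.seed(515)
    founders <- simulate_founders(2 * sum(ped$sire == 0), map)
    gd <- gene_drop(ped, founders, map)
    dos <- gd$mat[ids, ] + gd$pat[ids, ]
    eig <- eigen(kinship_submatrix(A, ids), symmetric = TRUE)
    sp <- match(ped$sire, ped$id, nomatch = 0L)
    dp <- match(ped$dam, ped$id, nomatch = 0L)
    hits <- 0; total <- 0
    for (r in seq_len(n_reps)) {
      u <- numeric(nrow(ped))
      for (i in seq_len(nrow(ped))) {
        u[i] <- if (sp[i] == 0L) rnorm(1, 0, sqrt(0.4)) else
          (u[sp[i]] + u[dp[i]]) / 2 + rnorm(1, 0, sqrt(0.2))
      }
      y <- u[match(as.integer(ids), ped$id)] + rnorm(length(ids),
                                                     0, sqrt(0.6))
      phe <- tibble::tibble(id = as.integer(ids), value = y)
      sc <- scan_mma(phe, dos, A, map, eig = eig)
      hits <- hits + sum(sc$p_value < 0.05, na.rm = TRUE)
      total <- total + sum(!is.na(sc$p_value))
    }
    hits / total
  })
}

# planted additive QTL (5% variance, full-size pedigree): fraction of
# seeds whose minimum-p SNP lands within 10 cM of the QTL
mma_recovery_hits <- function() {
  cache_get("mma_recovery", vapply(1:20, function(s) {
    st <- big_chrom_study(300 + s, truth_row(pos = 30, frac = 0.05))
    sc <- scan_mma(st$sim$phenotypes, dosage_matrix(st$sim), st$A,
                   st$sim$map, eig = st$eig)
    abs(sc$pos_cM[which.min(sc$p_value)] - 30) <= 10
  }, TRUE))
}

rhm_clade_hits <- function() {
  cache_get("rhm_recovery", vapply(1:20, function(s) {
    d <- sim_clade_qtl(500 + s, frac = 0.08, map = genetic_map(1, 60, 1))
    sc <- scan_rhm(d$phenotypes, d$phased, d$A, d$map, size = 4)
    abs(sc$pos_cM[which.min(sc$p_value)] - d$pos) <= 10
  }, TRUE))
}

genmix_clade_hits <- function() {
  cache_get("genmix_recovery", vapply(1:20, function(s) {
    d <- sim_clade_qtl(700 + s, frac = 0.08, map = genetic_map(1, 60, 1))
    sc <- scan_genmix(d$phenotypes, d$phased, d$A, d$map, levels = 3)
    abs(sc$pos_cM[which.min(sc$p_value)] - d$pos) <= 10
  }, TRUE))
}

bvs_recovery_hits <- function() {
  cache_get("bvs_recovery", vapply(1:10, function(s) {
    st <- big_chrom_study(3000 + s, truth_row(pos = 30, frac = 0.10))
    dos <- dosage_matrix(st$sim)
    f <- gibbs_bvs(st$sim$phenotypes, dos, map = st$sim$map,
                   iterations = 3000, burn_in = 1000, thin = 2,
                   seed = 4000 + s)
    top <- which.max(f$pip)
    f$pip[top] > 0.10 && abs(f$pos_cM[top] - 30) <= 10
  }, TRUE))
}

# conditional scan of the epistatic pair: does the second member's best
# signal drop once the first member's nearest SNP is in the model?
conditional_masking_drops <- function() {
  cache_get("cond_masking", vapply(1:20, function(s) {
    tr <- tibble::tibble(
      qtl = 1:2, chrom = 1L, pos_cM = c(36.30, 99.20),
      architecture = "epistatic_pair_member", partner = c(2L, 1L),
      target_fraction = c(0.03, 0.015), epi_fraction = c(0.04, NA)
    )
    st <- big_chrom_study(800 + s, tr, n_snp = 300, spacing = 1 / 3)
    dos <- dosage_matrix(st$sim)
    map <- st$sim$map
    marg <- scan_mma(st$sim$phenotypes, dos, st$A, map, eig = st$eig)
    j1 <- which.min(abs(map$pos_cM - 36.30))
    cond <- conditional_scan(st$sim$phenotypes, dos, st$A, map,
                             condition_on = map$snp[j1], chromosome = 1,
                             eig = st$eig)
    near2 <- abs(map$pos_cM - 99.20) <= 10
    best_marg <- max(marg$neg_log10_p[near2], na.rm = TRUE)
    best_cond <- max(cond$neg_log10_p[near2], na.rm = TRUE)
    best_cond < best_marg
  }, TRUE))
}
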