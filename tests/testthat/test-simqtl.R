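test_that("founder panel LD follows the chain strength", {
  map <- genetic_map(1, 100, 0.5)
  # independence limit
  H0 <- simulate_founders(400, map, ld_strength = 0, seed = 1)
  r0 <- vapply(seq_len(99), function(j) {
    if (var(H0[, j]) == 0 || var(H0[, j + 1]) == 0) return(0)
    cor(H0[, j], H0[, j + 1])
  }, 0)
  expect_lt(max(abs(r0)), 0.25)   # per-pair noise bound at n = 400
  expect_lt(abs(mean(r0)), 0.05)

  # determinism
  H0b <- simulate_founders(400, map, ld_strength = 0, seed = 1)
  expect_identical(H0, H0b)

  # stronger chain -> higher mean adjacent r^2, by direct computation
  r2 <- function(H) {
    mean(vapply(seq_len(ncol(H) - 1), function(j) {
      if (var(H[, j]) == 0 || var(H[, j + 1]) == 0) return(0)
      cor(H[, j], H[, j + 1])^2
    }, 0))
  }
  H_lo <- simulate_founders(400, map, ld_strength = 0.2, seed = 2)
  H_hi <- simulate_founders(400, map, ld_strength = 0.9, seed = 2)
  expect_gt(r2(H_hi), r2(H_lo))
})

test_that("founder panel respects the MAF floor", {
  map <- genetic_map(1, 200, 0.5)
  H <- simulate_founders(100, map, maf_floor = 0.1, seed = 5)
  f <- colMeans(H)
  expect_gte(min(pmin(f, 1 - f)), 0.1)
  expect_error(simulate_founders(100, map, maf_floor = 0.6), "maf_floor")
  expect_error(simulate_founders(101, map), "even|%%")
})

test_that("gene drop copies parents exactly when recombination is impossible", {
  # single-SNP chromosome has length 0 cM: gametes are exact parental copies
  map <- genetic_map(3, 1, 1)
  ped <- build_pedigree(1, 1, 6, 6)
  H <- matrix(rbinom(2 * 2 * 3, 1, 0.5), 4, 3)
  gd <- gene_drop(ped, H, map, seed = 4)
  for (i in 3:8) {
    for (j in 1:3) {
      expect_true(gd$mat[i, j] %in% c(gd$mat[2, j], gd$pat[2, j]))
      expect_true(gd$pat[i, j] %in% c(gd$mat[1, j], gd$pat[1, j]))
    }
  }
})

test_that("offspring of a homozygous parent copy that parent's haplotype", {
  map <- genetic_map(1, 50, 2)
  ped <- build_pedigree(1, 1, 10, 10)
  H <- rbind(rep(1L, 50), rep(1L, 50),          # sire: homozygous 1
             rbinom(50, 1, 0.5), rbinom(50, 1, 0.5))
  gd <- gene_drop(ped, H, map, seed = 8)
  prog <- as.character(ped$id[ped$generation == "progeny"])
  expect_true(all(gd$pat[prog, ] == 1L))
})

test_that("crossover counts are Poisson with the map length in Morgans", {
  map <- genetic_map(1, 1998, 0.05)   # 99.85 cM
  ped <- build_pedigree(1, 1, 5000, 1)
  # heterozygous-everywhere parents: gamete switches reveal crossovers
  H <- rbind(rep(0L, 1998), rep(1L, 1998), rep(0L, 1998), rep(1L, 1998))
  gd <- gene_drop(ped, H, map, seed = 12)
  prog <- ped$generation == "progeny"
  switches <- function(g) sum(diff(g) != 0)
  xo <- c(apply(gd$mat[prog, ], 1, switches),
          apply(gd$pat[prog, ], 1, switches))
  m <- 0.9985
  se <- sqrt(m / length(xo))
  expect_lt(abs(mean(xo) - m), 3 * se)
})

test_that("every offspring allele is Mendelian-consistent", {
  map <- genetic_map(2, 40, 1)
  sim <- simulate_qtlmas(seed = 31, n_sires = 3, n_dams_per_sire = 2,
                         n_progeny_per_family = 3,
                         n_phenotyped_per_family = 2,
                         map = map, truth = empty_truth())
  ped <- sim$pedigree
  for (i in which(ped$sire != 0)) {
    id <- as.character(ped$id[i])
    s <- as.character(ped$sire[i]); d <- as.character(ped$dam[i])
    expect_true(all(sim$haplos$pat[id, ] == sim$haplos$mat[s, ] |
                      sim$haplos$pat[id, ] == sim$haplos$pat[s, ]))
    expect_true(all(sim$haplos$mat[id, ] == sim$haplos$mat[d, ] |
                      sim$haplos$mat[id, ] == sim$haplos$pat[d, ]))
  }
})

test_that("multi-allelic QTL labels cover the allele domain", {
  map <- genetic_map(1, 50, 1)
  lab <- assign_multiallelic_qtl(400, map, 1, 20, n_alleles = 3, seed = 2)
  expect_setequal(unique(lab), 1:3)
  expect_length(lab, 400)
  expect_error(assign_multiallelic_qtl(400, map, 1, 20, n_alleles = 1),
               "n_alleles")
  expect_error(assign_multiallelic_qtl(400, map, 1, 500), "outside")
})

test_that("no single SNP perfectly tags a 3-allele QTL", {
  sim <- default_sim_cached()
  ids <- as.character(sim$phenotypes$id)
  # one-vs-rest indicators of the QTL alleles on the maternal gamete
  lab <- sim$qtl_labels$mat[ids]
  chr1 <- which(sim$map$chrom == 1)
  G <- sim$haplos$mat[ids, chr1]
  best <- 0
  for (a in sort(unique(lab))) {
    ind <- as.integer(lab == a)
    r2 <- (cor(G, ind))^2
    best <- max(best, max(r2, na.rm = TRUE))
  }
  expect_lt(best, 1)
})

test_that("null phenotype model leaves pure residual variance", {
  map <- genetic_map(1, 30, 1)
  sim <- simulate_qtlmas(seed = 17, n_sires = 10, n_dams_per_sire = 10,
                         n_progeny_per_family = 2,
                         n_phenotyped_per_family = 2,
                         map = map, truth = empty_truth(),
                         h2_polygenic = 0)
  expect_equal(var(sim$phenotypes$value), 1, tolerance = 0.10)
})

test_that("variance budget above one is rejected", {
  map <- genetic_map(1, 30, 1)
  expect_error(
    simulate_qtlmas(seed = 1, n_sires = 2, n_dams_per_sire = 2,
                    n_progeny_per_family = 2, n_phenotyped_per_family = 2,
                    map = map, truth = truth_row(frac = 0.9),
                    h2_polygenic = 0.3),
    "budget")
})

test_that("chromosome-1 QTL explains about its anchored variance share", {
  sim <- default_sim_cached()
  ids <- as.character(sim$phenotypes$id)
  lm_ <- factor(sim$qtl_labels$mat[ids])
  lp_ <- factor(sim$qtl_labels$pat[ids])
  r2 <- summary(lm(sim$phenotypes$value ~ lm_ + lp_))$r.squared
  expect_equal(r2, 0.102, tolerance = 0.03 / 0.102)  # within 3 points
  # realised fraction bookkeeping stays within 20% of target
  ok <- abs(sim$truth$realized_fraction - sim$truth$target_fraction) /
    sim$truth$target_fraction
  expect_true(all(ok < 0.20))
})

test_that("imprinted QTL acts through the paternal allele only", {
  sim <- default_sim_cached()
  ids <- as.character(sim$phenotypes$id)
  k <- which(sim$truth$architecture == "imprinted")
  j <- pedgwas:::qtl_snp_index(sim$map, sim$truth$chrom[k],
                               sim$truth$pos_cM[k])
  pat <- sim$haplos$pat[ids, j]
  mat <- sim$haplos$mat[ids, j]
  y <- sim$phenotypes$value
  fit <- lm(y ~ pat + mat)
  ct <- summary(fit)$coefficients
  expect_lt(abs(ct["mat", "t value"]), 3)   # maternal slope ~ 0
  expect_gt(abs(ct["pat", "t value"]), 4)   # paternal slope real
})

test_that("the second epistatic QTL is masked by the first", {
  sim <- default_sim_cached()
  ids <- as.character(sim$phenotypes$id)
  k1 <- which(!is.na(sim$truth$epi_fraction))
  k2 <- sim$truth$partner[k1]
  j1 <- pedgwas:::qtl_snp_index(sim$map, sim$truth$chrom[k1],
                                sim$truth$pos_cM[k1])
  j2 <- pedgwas:::qtl_snp_index(sim$map, sim$truth$chrom[k2],
                                sim$truth$pos_cM[k2])
  x1 <- sim$haplos$mat[ids, j1] + sim$haplos$pat[ids, j1]
  x2 <- sim$haplos$mat[ids, j2] + sim$haplos$pat[ids, j2]
  y <- sim$phenotypes$value
  marginal <- abs(cor(x2, y))
  partial <- abs(cor(resid(lm(x2 ~ x1)), resid(lm(y ~ x1))))
  expect_lt(partial, marginal)
})

test_that("identical seed and parameters give identical studies", {
  map <- genetic_map(1, 40, 1)
  s1 <- simulate_qtlmas(seed = 23, n_sires = 3, n_dams_per_sire = 2,
                        n_progeny_per_family = 3,
                        n_phenotyped_per_family = 2, map = map,
                        truth = truth_row(frac = 0.1))
  s2 <- simulate_qtlmas(seed = 23, n_sires = 3, n_dams_per_sire = 2,
                        n_progeny_per_family = 3,
                        n_phenotyped_per_family = 2, map = map,
                        truth = truth_row(frac = 0.1))
  expect_identical(s1$haplos, s2$haplos)
  expect_identical(s1$phenotypes, s2$phenotypes)
  s3 <- simulate_qtlmas(seed = 24, n_sires = 3, n_dams_per_sire = 2,
                        n_progeny_per_family = 3,
                        n_phenotyped_per_family = 2, map = map,
                        truth = truth_row(frac = 0.1))
  expect_false(identical(s1$phenotypes$value, s3$phenotypes$value))
})
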