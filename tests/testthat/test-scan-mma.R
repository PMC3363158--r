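make_null_scan_data <- function(seed, n_snp = 100) {
  st <- small_study(seed, empty_truth(), map = genetic_map(1, n_snp, 1))
  list(sim = st$sim, A = st$A, dosage = dosage_matrix(st$sim))
}

test_that("with A = I the scan reduces to ordinary per-SNP regression", {
  d <- make_null_scan_data(41, n_snp = 30)
  ids <- rownames(d$dosage)
  n <- length(ids)
  I <- diag(n); dimnames(I) <- list(ids, ids)
  sc <- scan_mma(d$sim$phenotypes, d$dosage, I, d$sim$map)
  y <- d$sim$phenotypes$value
  for (j in c(1, 7, 19, 30)) {
    x <- d$dosage[, j]
    if (var(x) == 0) next
    f <- summary(lm(y ~ x))$coefficients
    expect_equal(sc$effect[j], f["x", "Estimate"], tolerance = 1e-8)
    # Wald chi-square(1) vs the same t-statistic squared
    expect_equal(sc$statistic[j], f["x", "t value"]^2, tolerance = 1e-6)
  }
})

test_that("swapping allele labels flips the effect and keeps the p-value", {
  d <- make_null_scan_data(43, n_snp = 25)
  sc1 <- scan_mma(d$sim$phenotypes, d$dosage, d$A, d$sim$map)
  flipped <- 2L - d$dosage
  rownames(flipped) <- rownames(d$dosage)
  sc2 <- scan_mma(d$sim$phenotypes, flipped, d$A, d$sim$map)
  ok <- sc1$estimable
  expect_lt(max(abs(sc1$effect[ok] + sc2$effect[ok])), 1e-8)
  expect_lt(max(abs(sc1$p_value[ok] - sc2$p_value[ok])), 1e-10)
})

test_that("monomorphic SNPs are flagged and excluded from the test count", {
  d <- make_null_scan_data(47, n_snp = 20)
  d$dosage[, 5] <- 1L
  sc <- scan_mma(d$sim$phenotypes, d$dosage, d$A, d$sim$map)
  expect_false(sc$estimable[5])
  expect_true(is.na(sc$p_value[5]))
  expect_equal(attr(sc, "n_tests"), 19)
})

test_that("a pure-noise phenotype yields no Bonferroni hits", {
  hits <- vapply(1:20, function(s) {
    d <- make_null_scan_data(100 + s, n_snp = 100)
    sc <- scan_mma(d$sim$phenotypes, d$dosage, d$A, d$sim$map, alpha = 0.05)
    sum(sc$significant, na.rm = TRUE) > 0
  }, TRUE)
  expect_gte(mean(!hits), 0.95)
})

test_that("a planted additive QTL is localised within 10 cM", {
  expect_gte(mean(mma_recovery_hits()), 0.90)
})

test_that("P3D and exact per-SNP refits agree on small effects", {
  st <- small_study(61, truth_row(pos = 30, frac = 0.04),
                    map = genetic_map(1, 40, 1))
  dos <- dosage_matrix(st$sim)
  s1 <- scan_mma(st$sim$phenotypes, dos, st$A, st$sim$map, refit = FALSE)
  s2 <- scan_mma(st$sim$phenotypes, dos, st$A, st$sim$map, refit = TRUE)
  ok <- s1$estimable
  expect_equal(s1$neg_log10_p[ok], s2$neg_log10_p[ok], tolerance = 0.05)
})

test_that("conditional scan reduces to the plain scan with no conditioning", {
  st <- small_study(53, truth_row(pos = 30, frac = 0.08),
                    map = genetic_map(1, 40, 1))
  dos <- dosage_matrix(st$sim)
  plain <- scan_mma(st$sim$phenotypes, dos, st$A, st$sim$map)
  cond <- conditional_scan(st$sim$phenotypes, dos, st$A, st$sim$map,
                           condition_on = character(), chromosome = 1)
  expect_lt(max(abs(plain$p_value - cond$p_value), na.rm = TRUE), 1e-10)
})

test_that("conditioning on the tested SNP itself is non-estimable", {
  st <- small_study(54, empty_truth(), map = genetic_map(1, 20, 1))
  dos <- dosage_matrix(st$sim)
  target <- colnames(dos)[3]
  cond <- conditional_scan(st$sim$phenotypes, dos, st$A, st$sim$map,
                           condition_on = target, chromosome = 1)
  expect_false(cond$estimable[cond$snp == target])
})

test_that("joint fit recovers planted variance shares", {
  st <- big_chrom_study(77, truth_row(pos = 30, frac = 0.10))
  dos <- dosage_matrix(st$sim)
  sc <- scan_mma(st$sim$phenotypes, dos, st$A, st$sim$map, eig = st$eig)
  top <- sc$snp[which.min(sc$p_value)]
  jf <- joint_fit(st$sim$phenotypes, dos, st$A, st$sim$map, top,
                  eig = st$eig)
  expect_equal(jf$var_explained_pct, 10, tolerance = 3 / 10)

  # two unlinked planted QTL: joint shares add up to the marginals
  tr2 <- dplyr::bind_rows(truth_row(pos = 20, frac = 0.08),
                          truth_row(pos = 80, frac = 0.06))
  tr2$qtl <- 1:2
  st2 <- big_chrom_study(78, tr2)
  dos2 <- dosage_matrix(st2$sim)
  sc2 <- scan_mma(st2$sim$phenotypes, dos2, st2$A, st2$sim$map,
                  eig = st2$eig)
  near <- function(pos) {
    cand <- which(abs(sc2$pos_cM - pos) <= 10)
    cand[which.min(sc2$p_value[cand])]
  }
  picks <- sc2$snp[c(near(20), near(80))]
  jf2 <- joint_fit(st2$sim$phenotypes, dos2, st2$A, st2$sim$map, picks,
                   eig = st2$eig)
  marg <- vapply(picks, function(s) {
    jf1 <- joint_fit(st2$sim$phenotypes, dos2, st2$A, st2$sim$map, s,
                     eig = st2$eig)
    jf1$var_explained_pct
  }, 0)
  expect_equal(sum(jf2$var_explained_pct), sum(marg), tolerance = 2 / 14)

  # a zero-effect SNP explains essentially nothing
  null_snp <- sc2$snp[which.max(abs(sc2$pos_cM - 50) < 1)]
  jf3 <- joint_fit(st2$sim$phenotypes, dos2, st2$A, st2$sim$map,
                   c(picks, null_snp), eig = st2$eig)
  expect_lt(jf3$var_explained_pct[jf3$snp == null_snp], 0.5)

  # empty detected list
  jf0 <- joint_fit(st2$sim$phenotypes, dos2, st2$A, st2$sim$map,
                   character())
  expect_equal(nrow(jf0), 0)
})
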