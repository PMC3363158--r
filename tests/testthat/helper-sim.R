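# shared fixtures, built once per test run
.pg_cache <- new.env(parent = emptyenv())

cache_get <- function(name, expr) {
  if (!exists(name, envir = .pg_cache)) {
    assign(name, force(expr), envir = .pg_cache)
  }
  get(name, envir = .pg_cache)
}

# full default-configuration study (2000 phenotyped, 9990 SNPs)
default_sim_cached <- function() {
  cache_get("default_sim", simulate_qtlmas(seed = 101))
}

# default pedigree with its relationship matrix and the eigendecomposition
# of the phenotyped block (the dominant shared cost of the big scans)
big_pedigree_cached <- function() {
  cache_get("big_ped", {
    ped <- build_pedigree()
    A <- additive_relationship(ped)
    ids <- as.character(ped$id[ped$phenotyped])
    eig <- eigen(kinship_submatrix(A, ids), symmetric = TRUE)
    list(ped = ped, A = A, ids = ids, eig = eig)
  })
}

truth_row <- function(chrom = 1L, pos = 30, arch = "additive",
                      frac = 0.05, partner = NA_integer_, epi = NA_real_) {
  tibble::tibble(qtl = 1L, chrom = as.integer(chrom), pos_cM = pos,
                 architecture = arch, partner = partner,
                 target_fraction = frac, epi_fraction = epi)
}

empty_truth <- function() truth_row()[0, ]

# one-chromosome study on the full-size pedigree, reusing the cached
# eigendecomposition (the pedigree itself is rebuilt deterministically)
big_chrom_study <- function(seed, truth, n_snp = 300, spacing = 1 / 3,
                            ...) {
  bp <- big_pedigree_cached()
  sim <- simulate_qtlmas(seed, map = genetic_map(1, n_snp, spacing),
                         truth = truth, ...)
  list(sim = sim, A = bp$A, eig = bp$eig)
}

# small study: 10 sires x 5 dams x 6 progeny, 200 phenotyped
small_study <- function(seed, truth, map = genetic_map(1, 80, 1), ...) {
  sim <- simulate_qtlmas(seed, n_sires = 10, n_dams_per_sire = 5,
                         n_progeny_per_family = 6,
                         n_phenotyped_per_family = 4,
                         map = map, truth = truth, ...)
  A <- additive_relationship(sim$pedigree)
  list(sim = sim, A = A)
}

# QTL whose effect follows one founder haplotype clade: the effect is
# attached to a shared local haplotype string (a window of SNPs at `pos`),
# so carriers form a clade of the local genealogy and share window labels
sim_clade_qtl <- function(seed, frac = 0.08, h2 = 0.3,
                          map = genetic_map(1, 80, 1), pos = 30,
                          window = 4, ld_strength = 0.98,
                          n_sires = 10, n_dams = 5, n_prog = 8,
                          n_phen = 8) {
  set.seed(seed)
  ped <- build_pedigree(n_sires, n_dams, n_prog, n_phen)
  nf <- sum(ped$sire == 0)
  founders <- simulate_founders(2 * nf, map, ld_strength = ld_strength)
  gd <- gene_drop(ped, founders, map)
  ids <- as.character(ped$id[ped$phenotyped])
  # carrier haplotype: the most common founder window string with
  # frequency nearest 1/3 (a mid-sized clade)
  j0 <- which.min(abs(map$pos_cM - pos))
  cols <- j0:min(j0 + window - 1, ncol(founders))
  key_of <- function(M) apply(M[, cols, drop = FALSE], 1, paste,
                              collapse = "")
  fk <- key_of(founders)
  tab <- table(fk) / length(fk)
  target_key <- names(tab)[which.min(abs(tab - 1 / 3))]
  z <- (key_of(gd$mat[ids, , drop = FALSE]) == target_key) +
    (key_of(gd$pat[ids, , drop = FALSE]) == target_key)
  zc <- z - mean(z)
  a <- if (var(zc) > 0) sqrt(frac / var(zc)) else 0
  u <- numeric(nrow(ped))
  sp <- match(ped$sire, ped$id, nomatch = 0L)
  dp <- match(ped$dam, ped$id, nomatch = 0L)
  for (i in seq_len(nrow(ped))) {
    u[i] <- if (sp[i] == 0L) rnorm(1, 0, sqrt(h2)) else
      (u[sp[i]] + u[dp[i]]) / 2 + rnorm(1, 0, sqrt(h2 / 2))
  }
  y <- a * zc + u[match(as.integer(ids), ped$id)] +
    rnorm(length(ids), 0, sqrt(1 - frac - h2))
  list(
    phenotypes = tibble::tibble(id = as.integer(ids), value = y),
    phased = list(mat = gd$mat[ids, , drop = FALSE],
                  pat = gd$pat[ids, , drop = FALSE]),
    dosage = gd$mat[ids, , drop = FALSE] + gd$pat[ids, , drop = FALSE],
    A = additive_relationship(ped), map = map, pos = pos
  )
}

# recombination-free binary haplotype matrices with unique mutation sites
sim_no_recomb_matrix <- function(n_hap = 24, n_site = 15, seed = 1) {
  set.seed(seed)
  H <- matrix(0L, n_hap, n_site)
  lineages <- list(seq_len(n_hap))
  for (j in seq_len(n_site)) {
    # pick a current lineage, split it by a fresh mutation
    li <- sample(seq_along(lineages), 1)
    grp <- lineages[[li]]
    if (length(grp) >= 2) {
      k <- sample(seq_len(length(grp) - 1), 1)
      carriers <- sample(grp, k)
      H[carriers, j] <- 1L
      lineages[[li]] <- setdiff(grp, carriers)
      lineages[[length(lineages) + 1]] <- carriers
    }
  }
  H
}
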