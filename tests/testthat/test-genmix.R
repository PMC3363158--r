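test_that("four-gamete condition counts observed gamete types", {
  expect_true(four_gamete_compatible(c(0, 0, 1), c(0, 1, 0)))
  expect_false(four_gamete_compatible(c(0, 0, 1, 1), c(0, 1, 0, 1)))
  expect_true(four_gamete_compatible(c(0, 1, 0, 1), c(0, 1, 0, 1)))
})

test_that("widest compatible region is maximal against brute force", {
  all_pairs_ok <- function(H, lo, hi) {
    if (lo == hi) return(TRUE)
    for (a in lo:(hi - 1)) {
      for (b in (a + 1):hi) {
        if (!four_gamete_compatible(H[, a], H[, b])) return(FALSE)
      }
    }
    TRUE
  }
  set.seed(91)
  for (rep in 1:6) {
    H <- matrix(rbinom(20 * 40, 1, runif(1, 0.2, 0.5)), 20, 40)
    for (focal in c(1, 13, 27, 40)) {
      iv <- widest_compatible_region(H, focal)
      expect_true(iv[1] <= focal && focal <= iv[2])
      # emitted interval is internally compatible ...
      expect_true(all_pairs_ok(H, iv[1], iv[2]))
      # ... and not extendable by one site on either end
      if (iv[1] > 1) {
        expect_false(all_pairs_ok(H, iv[1] - 1, iv[2]))
      }
      if (iv[2] < 40) {
        expect_false(all_pairs_ok(H, iv[1], iv[2] + 1))
      }
    }
  }
})

test_that("identical columns span the whole chromosome", {
  H <- matrix(rep(rbinom(12, 1, 0.5), 8), 12, 8)
  expect_equal(unname(widest_compatible_region(H, 4)), c(1, 8))
})

test_that("a focal site flanked by incompatible sites stays alone", {
  # columns engineered so both neighbours show all four gametes with focal
  f <- c(0, 0, 1, 1)
  bad <- c(0, 1, 0, 1)
  H <- cbind(bad, f, bad)
  expect_equal(unname(widest_compatible_region(H, 2)), c(2, 2))
})

test_that("perfect phylogeny puts derived carriers on single subtrees", {
  collect_nodes <- function(nd, acc = list()) {
    acc[[length(acc) + 1]] <- nd
    for (ch in nd$children) acc <- collect_nodes(ch, acc)
    acc
  }
  for (s in 1:5) {
    H <- sim_no_recomb_matrix(n_hap = 24, n_site = 15, seed = s)
    # compatible by construction
    iv <- widest_compatible_region(H, 1)
    expect_equal(unname(iv), c(1, ncol(H)))
    tree <- build_perfect_phylogeny(H)
    nodes <- collect_nodes(tree$root)
    node_sets <- lapply(nodes, function(nd) {
      unname(sort(unlist(tree$leaf_groups[nd$groups])))
    })
    for (j in seq_len(ncol(H))) {
      n1 <- sum(H[, j])
      if (n1 == 0 || n1 == nrow(H)) next
      derived <- if (n1 * 2 > nrow(H)) 0L else 1L
      carrier_set <- sort(which(H[, j] == derived))
      expect_true(any(vapply(node_sets, identical, TRUE, carrier_set)))
    }
    # one leaf group per distinct haplotype
    expect_equal(length(tree$leaf_groups),
                 nrow(unique(as.data.frame(H))))
  }
})

test_that("forced topologies come out as specified", {
  # single segregating site: carriers vs non-carriers
  H <- matrix(c(1, 1, 0, 0, 0), 5, 1)
  t1 <- build_perfect_phylogeny(H)
  expect_equal(length(t1$leaf_groups), 2)
  cl <- enumerate_clusterings(t1, 3)
  expect_length(cl, 1)
  expect_equal(sort(unique(cl[[1]]$labels)), 1:2)

  # nested carrier sets {h1,h2} in {h1,h2,h3}: chain, three leaf groups
  H2 <- cbind(c(1, 1, 1, 0, 0), c(1, 1, 0, 0, 0))
  t2 <- build_perfect_phylogeny(H2)
  expect_equal(length(t2$leaf_groups), 3)
})

test_that("the three-level cut scheme yields up to seven clusterings", {
  carrier <- list(1:4, 5:8, 1:2, 3:4, 5:6, 7:8, 1, 3, 5, 7)
  H <- matrix(0L, 8, length(carrier))
  for (j in seq_along(carrier)) H[carrier[[j]], j] <- 1L
  tree <- build_perfect_phylogeny(H)
  cl <- enumerate_clusterings(tree, levels = 3)
  expect_length(cl, 7)
  expect_equal(sum(vapply(cl, `[[`, 0L, "level") == 1L), 1L)
  expect_equal(sum(vapply(cl, `[[`, 0L, "level") == 2L), 2L)
  expect_equal(sum(vapply(cl, `[[`, 0L, "level") == 3L), 4L)
  # the top split has 2 clusters, the others 3
  sizes <- vapply(cl, function(x) length(unique(x$labels)), 0L)
  expect_equal(sort(sizes), c(2, rep(3, 6)))
  # fewer levels truncate the list
  expect_length(enumerate_clusterings(tree, levels = 1), 1)
  expect_length(enumerate_clusterings(tree, levels = 2), 3)
})

test_that("every clustering partitions the full haplotype set", {
  set.seed(17)
  for (rep in 1:20) {
    H <- sim_no_recomb_matrix(n_hap = sample(10:30, 1),
                              n_site = sample(5:20, 1), seed = 1000 + rep)
    tree <- build_perfect_phylogeny(H)
    if (length(tree$leaf_groups) < 2) next
    for (cl in enumerate_clusterings(tree, 3)) {
      expect_length(cl$labels, nrow(H))
      expect_true(all(cl$labels %in% 1:3))
      expect_gte(length(unique(cl$labels)), 2)
    }
  }
})

test_that("degenerate trees give an empty clustering list", {
  H <- matrix(1L, 6, 3)
  tree <- build_perfect_phylogeny(H)
  expect_warning(cl <- enumerate_clusterings(tree, 3), "degenerate")
  expect_length(cl, 0)
})

test_that("cluster label swaps leave the fitted model unchanged", {
  st <- small_study(83, truth_row(pos = 10, frac = 0.08),
                    map = genetic_map(1, 12, 1))
  ph <- phased_genotypes(st$sim)
  n <- nrow(ph$mat)
  ids <- rownames(ph$mat)
  y <- st$sim$phenotypes$value[match(ids, as.character(st$sim$phenotypes$id))]
  eig <- eigen(kinship_submatrix(st$A, ids), symmetric = TRUE)
  d <- pmax(eig$values, 0); U <- eig$vectors
  yt <- crossprod(U, y)[, 1]; Ot <- crossprod(U, matrix(1, n, 1))
  H <- matrix(0L, 2 * n, 12)
  H[seq(1, 2 * n, 2), ] <- ph$mat
  H[seq(2, 2 * n, 2), ] <- ph$pat
  iv <- widest_compatible_region(H, 6)
  tree <- build_perfect_phylogeny(H[, iv[1]:iv[2], drop = FALSE])
  cl <- enumerate_clusterings(tree, 3)
  three <- Filter(function(x) length(unique(x$labels)) == 3, cl)
  if (length(three) > 0) {
    lab <- three[[1]]$labels
    swapped <- c(1L, 3L, 2L)[lab]
    for (mode in c("class", "hap")) {
      Z1 <- pedgwas:::clustering_incidence(lab, n, mode)
      Z2 <- pedgwas:::clustering_incidence(swapped, n, mode)
      f1 <- pedgwas:::reml_2k_lowrank(yt, Ot, d, crossprod(U, Z1))
      f2 <- pedgwas:::reml_2k_lowrank(yt, Ot, d, crossprod(U, Z2))
      expect_lt(abs(f1$loglik - f2$loglik), 1e-6)
    }
  }
})

test_that("genmix scan localises a clade-driven QTL within 10 cM", {
  expect_gte(mean(genmix_clade_hits()), 0.80)
})

test_that("strict multiple-testing mode is never more permissive", {
  for (s in 1:6) {
    st <- small_study(900 + s, empty_truth(), map = genetic_map(1, 40, 1))
    ph <- phased_genotypes(st$sim)
    lax <- scan_genmix(st$sim$phenotypes, ph, st$A, st$sim$map,
                       strict_mt = FALSE)
    strict <- scan_genmix(st$sim$phenotypes, ph, st$A, st$sim$map,
                          strict_mt = TRUE)
    expect_lte(sum(strict$significant), sum(lax$significant))
    expect_lte(attr(strict, "threshold"), attr(lax, "threshold"))
    # reported p is the minimum over that marker's clusterings
    expect_true(all(lax$p_value <= 1 & lax$p_value > 0))
  }
})
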