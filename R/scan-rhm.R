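#' Enumerate sliding haplotype windows
#'
#' One window per start index `1..(M - size + 1)` per chromosome; the
#' window midpoint (mean cM of its first and last SNP) is the putative QTL
#' position reported for a significant window.  Chromosomes with fewer
#' SNPs than `size` are skipped with a warning.
#'
#' @param map Map tibble.
#' @param size Window size in SNPs (default 4).
#' @return Tibble with `chrom`, `start` (genome-wide column index of the
#'   first SNP), `start_idx` (within-chromosome), `size`, `mid_cM`.
#' @export
make_windows <- function(map, size = 4) {
  stopifnot(size >= 1)
  out <- lapply(unique(map$chrom), function(ch) {
    cols <- which(map$chrom == ch)
    m <- length(cols)
    if (m < size) {
      warning("chromosome ", ch, " has ", m, " SNPs < window size ", size,
              "; skipped")
      return(NULL)
    }
    starts <- seq_len(m - size + 1L)
    tibble::tibble(
      chrom = ch,
      start = cols[starts],
      start_idx = starts,
      size = size,
      mid_cM = (map$pos_cM[cols[starts]] +
                  map$pos_cM[cols[starts + size - 1L]]) / 2
    )
  })
  dplyr::bind_rows(out)
}

# integer label per gamete for one window: distinct observed allele strings
window_labels <- function(mat, pat, cols) {
  pow <- 2^(seq_along(cols) - 1)
  cm <- as.vector(mat[, cols, drop = FALSE] %*% pow)
  cp <- as.vector(pat[, cols, drop = FALSE] %*% pow)
  codes <- sort(unique(c(cm, cp)))
  list(mat = match(cm, codes), pat = match(cp, codes), q = length(codes))
}

#' Random haplotype model scan (sliding windows, boundary LRT)
#'
#' For every sliding window of `size` SNPs, fits the mixed model
#' `y = mu + u + q_m + q_p + e`, where `q_m`/`q_p` are i.i.d. random
#' effects of the maternal and paternal window haplotype labels with a
#' common variance `sigma_h^2` (equal maternal/paternal variance), and `u`
#' is the pedigree polygenic effect.  The window is tested against the
#' null model without haplotype effects by a likelihood-ratio test at the
#' variance boundary (p-values from the half-half chi-square mixture).
#' Significance is Bonferroni-corrected over the number of windows tested.
#'
#' @param phenotypes Tibble with `id`, `value`.
#' @param phased List with `mat`/`pat` 0/1 matrices of the analysed
#'   individuals (rownames = ids).
#' @param A Additive relationship matrix.
#' @param map Map tibble aligned to the matrix columns.
#' @param size Window size in SNPs.
#' @param alpha Experiment-wise significance level.
#' @param boundary Use the boundary chi-square mixture (default) or plain
#'   chi-square(1).
#' @param min_label_count Pool haplotype labels observed fewer times than
#'   this into a single rare class (0 = no pooling, the default; random
#'   effects already shrink rare labels).
#' @param eig Optional pre-computed eigendecomposition of the id-subset
#'   of `A`.
#'
#' @return A `pg_scan` tibble with one row per window: `chrom`, `pos_cM`
#'   (window midpoint), `window` id, `n_labels`, `sigma2_h`, `statistic`
#'   (LRT), `p_value`, `neg_log10_p`, `significant`.
#' @export
scan_rhm <- function(phenotypes, phased, A, map, size = 4, alpha = 0.05,
                     boundary = TRUE, min_label_count = 0, eig = NULL) {
  ids <- rownames(phased$mat)
  y <- phenotypes$value[match(ids, as.character(phenotypes$id))]
  if (anyNA(y)) stop("individuals without phenotype records", call. = FALSE)
  if (is.null(eig)) eig <- eigen(kinship_submatrix(A, ids), symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  yt <- crossprod(U, y)[, 1]
  Ot <- crossprod(U, matrix(1, length(y), 1))
  n <- length(y)

  null <- reml_1k(yt, Ot, d)
  loglu <- log(max(null$lambda, 1e-9))

  windows <- make_windows(map, size)
  fit_one <- function(w) {
    cols <- w$start + seq_len(w$size) - 1L
    lab <- window_labels(phased$mat, phased$pat, cols)
    if (min_label_count > 0) {
      cnt <- tabulate(c(lab$mat, lab$pat), lab$q)
      rare <- which(cnt < min_label_count)
      if (length(rare) > 1) {
        remap <- seq_len(lab$q)
        remap[rare] <- rare[1]
        remap <- match(remap, sort(unique(remap)))
        lab$mat <- remap[lab$mat]; lab$pat <- remap[lab$pat]
        lab$q <- max(remap)
      }
    }
    if (lab$q < 2) {
      return(c(q = lab$q, s2h = 0, lrt = 0, p = 1))
    }
    Z <- matrix(0, n, lab$q)
    Z[cbind(seq_len(n), lab$mat)] <- Z[cbind(seq_len(n), lab$mat)] + 1
    Z[cbind(seq_len(n), lab$pat)] <- Z[cbind(seq_len(n), lab$pat)] + 1
    Zt <- crossprod(U, Z)
    full <- reml_2k_lowrank(yt, Ot, d, Zt, init_loglam_u = loglu)
    ll_full <- max(full$loglik, null$loglik)
    lrt <- max(0, 2 * (ll_full - null$loglik))
    c(q = lab$q, s2h = full$sigma2_h,
      lrt = lrt, p = lrt_pvalue(ll_full, null$loglik, boundary = boundary))
  }
  res <- t(vapply(seq_len(nrow(windows)),
                  function(i) fit_one(windows[i, ]), numeric(4)))

  n_tests <- nrow(windows)
  thr <- bonferroni_threshold(alpha, max(n_tests, 1))
  out <- tibble::tibble(
    window = paste0("c", windows$chrom, "_w", windows$start_idx),
    chrom = windows$chrom, pos_cM = windows$mid_cM,
    n_labels = as.integer(res[, "q"]),
    sigma2_h = res[, "s2h"],
    statistic = res[, "lrt"], p_value = res[, "p"],
    neg_log10_p = -log10(res[, "p"]),
    estimable = TRUE,
    significant = res[, "p"] < thr
  )
  new_scan(out, method = "rhm", alpha = alpha, n_tests = n_tests,
           threshold = thr,
           null_fit = c(sigma2_u = null$sigma2_u, sigma2_e = null$sigma2_e,
                        loglik = null$loglik))
}

#' Resolve phase from parent genotypes where unambiguous (trio phasing)
#'
#' A utility for realism experiments: given unphased offspring dosages and
#' parental dosages, recovers the maternal/paternal allele at every site
#' where transmission is unambiguous (offspring homozygous, or exactly one
#' parent able to donate a given allele); ambiguous sites are returned as
#' `NA`.
#'
#' @param offspring,sire,dam Dosage vectors (0/1/2) over the same SNPs.
#' @return List with `mat`/`pat` vectors in `{0, 1, NA}`.
#' @export
trio_phase <- function(offspring, sire, dam) {
  n <- length(offspring)
  mat <- pat <- rep(NA_integer_, n)
  hom <- offspring != 1L
  mat[hom] <- pat[hom] <- as.integer(offspring[hom] / 2L)
  het <- which(offspring == 1L)
  for (i in het) {
    s_can <- if (sire[i] == 0L) 0L else if (sire[i] == 2L) 1L else 0:1
    d_can <- if (dam[i] == 0L) 0L else if (dam[i] == 2L) 1L else 0:1
    ok <- expand.grid(p = s_can, m = d_can)
    ok <- ok[ok$p + ok$m == 1L, , drop = FALSE]
    if (nrow(ok) == 1L) {
      pat[i] <- ok$p; mat[i] <- ok$m
    }
  }
  list(mat = mat, pat = pat)
}
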