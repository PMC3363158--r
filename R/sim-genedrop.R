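#' Drop founder haplotypes through a pedigree
#'
#' Simulates meiosis down the pedigree: every progeny gamete is a
#' recombinant of the transmitting parent's two gametes, with a
#' Poisson(map length in Morgans) crossover count per chromosome and
#' uniform crossover positions (Haldane model, no interference).  Phase is
#' tracked throughout: the `mat` gamete of an individual came from its dam,
#' the `pat` gamete from its sire.  Founder `i` receives rows `2i-1`
#' (maternal) and `2i` (paternal) of the founder panel.
#'
#' Additional non-SNP loci (for example multi-allelic QTL labels) can be
#' transmitted alongside the SNPs by giving their positions and founder
#' alleles; they recombine with the SNPs according to their cM position.
#'
#' @param pedigree Pedigree tibble, parents before offspring.
#' @param founder_haplotypes Matrix with two rows per founder, columns
#'   aligned to `map`.
#' @param map Genetic map tibble.
#' @param seed Optional integer seed.
#' @param extra_pos Optional tibble (`chrom`, `pos_cM`) of extra loci.
#' @param extra_alleles Matrix of founder alleles for the extra loci, two
#'   rows per founder, one column per extra locus.
#'
#' @return A list with integer matrices `mat` and `pat`
#'   (individuals x SNPs, rownames = ids) and, when extra loci are given,
#'   `extra_mat` and `extra_pat`.
#' @export
gene_drop <- function(pedigree, founder_haplotypes, map, seed = NULL,
                      extra_pos = NULL, extra_alleles = NULL) {
  check_pedigree_order(pedigree)
  founders <- which(pedigree$sire == 0 & pedigree$dam == 0)
  nf <- length(founders)
  if (nrow(founder_haplotypes) != 2 * nf) {
    stop("founder panel has ", nrow(founder_haplotypes),
         " haplotypes but the pedigree has ", nf, " founders", call. = FALSE)
  }
  if (ncol(founder_haplotypes) != nrow(map)) {
    stop("founder panel columns do not match the map", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(pedigree)
  M <- nrow(map)
  n_extra <- if (is.null(extra_pos)) 0L else nrow(extra_pos)

  chroms <- unique(map$chrom)
  chr_info <- lapply(chroms, function(ch) {
    cols <- which(map$chrom == ch)
    epos <- if (n_extra) which(extra_pos$chrom == ch) else integer()
    pos <- c(map$pos_cM[cols], if (length(epos)) extra_pos$pos_cM[epos])
    list(cols = cols, extra = epos, pos = pos,
         lo = min(pos), len = max(pos) - min(pos))
  })

  mat <- matrix(0L, n, M); pat <- matrix(0L, n, M)
  emat <- if (n_extra) matrix(0L, n, n_extra) else NULL
  epat <- if (n_extra) matrix(0L, n, n_extra) else NULL

  # one meiosis: recombine parent's two genome-wide gametes
  meiosis <- function(g1, g2, e1, e2) {
    out <- g1; eout <- e1
    for (ci in chr_info) {
      n_xo <- rpois(1, ci$len / 100)
      start <- sample.int(2L, 1L)
      if (n_xo == 0) {
        src <- rep(start, length(ci$pos))
      } else {
        xo <- sort(runif(n_xo, ci$lo, ci$lo + ci$len))
        src <- 1L + (start - 1L + findInterval(ci$pos, xo)) %% 2L
      }
      m <- length(ci$cols)
      s_snp <- src[seq_len(m)]
      take2 <- ci$cols[s_snp == 2L]
      out[take2] <- g2[take2]
      if (length(ci$extra)) {
        s_ex <- src[m + seq_along(ci$extra)]
        tke <- ci$extra[s_ex == 2L]
        eout[tke] <- e2[tke]
      }
    }
    list(g = out, e = eout)
  }

  sp <- match(pedigree$sire, pedigree$id, nomatch = 0L)
  dp <- match(pedigree$dam, pedigree$id, nomatch = 0L)
  fidx <- match(seq_len(n), founders)  # founder rank or NA
  no_extra <- integer(n_extra)
  for (i in seq_len(n)) {
    if (!is.na(fidx[i])) {
      mat[i, ] <- founder_haplotypes[2L * fidx[i] - 1L, ]
      pat[i, ] <- founder_haplotypes[2L * fidx[i], ]
      if (n_extra) {
        emat[i, ] <- extra_alleles[2L * fidx[i] - 1L, ]
        epat[i, ] <- extra_alleles[2L * fidx[i], ]
      }
    } else {
      d <- dp[i]; s <- sp[i]
      gm <- meiosis(mat[d, ], pat[d, ],
                    if (n_extra) emat[d, ] else no_extra,
                    if (n_extra) epat[d, ] else no_extra)
      gp <- meiosis(mat[s, ], pat[s, ],
                    if (n_extra) emat[s, ] else no_extra,
                    if (n_extra) epat[s, ] else no_extra)
      mat[i, ] <- gm$g; pat[i, ] <- gp$g
      if (n_extra) {
        emat[i, ] <- gm$e; epat[i, ] <- gp$e
      }
    }
  }
  rownames(mat) <- rownames(pat) <- pedigree$id
  if (!is.null(map$snp)) colnames(mat) <- colnames(pat) <- map$snp
  out <- list(mat = mat, pat = pat)
  if (n_extra) {
    rownames(emat) <- rownames(epat) <- pedigree$id
    out$extra_mat <- emat; out$extra_pat <- epat
  }
  out
}
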