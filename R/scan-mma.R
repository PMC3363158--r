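#' Single-SNP mixed-model association scan
#'
#' Tests every SNP for association with the phenotype under the linear
#' mixed model `y = 1 mu + x g + u + e`, with `x` the 0/1/2 allele dosage,
#' `u ~ N(0, A sigma_u^2)` the pedigree polygenic effect and
#' `e ~ N(0, I sigma_e^2)`.  The SNP effect is tested by a Wald
#' chi-square(1) test; genome-wide significance uses a Bonferroni
#' correction over the number of estimable markers.
#'
#' By default the polygenic and residual variances are estimated once
#' under the no-SNP null model and reused for every SNP (the
#' population-parameters-previously-determined shortcut standard in
#' large-scale mixed-model GWAS); `refit = TRUE` re-estimates them per SNP.
#'
#' @param phenotypes Tibble with `id`, `value`.
#' @param dosage Dosage matrix (individuals x SNPs, rownames = ids,
#'   colnames = SNP names).
#' @param A Additive relationship matrix covering the ids.
#' @param map Map tibble aligned to the dosage columns.
#' @param alpha Experiment-wise significance level.
#' @param refit Re-estimate variance components for every SNP.
#' @param eig Optional pre-computed eigendecomposition of `A` restricted
#'   to the scanned ids (saves the dominant cost across repeated scans).
#'
#' @return A `pg_scan` tibble: `snp`, `chrom`, `pos_cM`, `effect` (allele
#'   substitution effect, dosage coding), `se`, `statistic`, `p_value`,
#'   `neg_log10_p`, `estimable`, `significant`.  Attributes: `method`,
#'   `alpha`, `n_tests`, `threshold` (per-test level), `null_fit`.
#' @export
scan_mma <- function(phenotypes, dosage, A, map, alpha = 0.05,
                     refit = FALSE, eig = NULL) {
  al <- align_scan_inputs(phenotypes, dosage, A, eig)
  n <- length(al$y)
  null <- reml_1k(al$yt, al$Ot, al$d)
  w <- 1 / (null$lambda * al$d + 1)

  if (!refit) {
    res <- wald_scan_vec(al$yt, al$Ot, al$Gt, w, n)
  } else {
    res <- lapply(seq_len(ncol(al$Gt)), function(j) {
      if (var(al$dosage[, j]) == 0) {
        return(c(NA, NA, NA, NA))
      }
      f <- reml_1k(al$yt, cbind(al$Ot, al$Gt[, j]), al$d)
      wj <- 1 / (f$lambda * al$d + 1)
      v <- wald_scan_vec(al$yt, al$Ot, al$Gt[, j, drop = FALSE], wj, n)
      c(v$effect, v$se, v$statistic, v$p_value)
    })
    res <- as.data.frame(do.call(rbind, res))
    names(res) <- c("effect", "se", "statistic", "p_value")
  }

  mono <- apply(dosage, 2, function(x) var(x) == 0)
  res$effect[mono] <- res$se[mono] <- res$statistic[mono] <-
    res$p_value[mono] <- NA_real_
  n_tests <- sum(!mono)
  thr <- bonferroni_threshold(alpha, max(n_tests, 1))

  out <- tibble::tibble(
    snp = colnames(dosage),
    chrom = map$chrom, pos_cM = map$pos_cM,
    effect = res$effect, se = res$se, statistic = res$statistic,
    p_value = res$p_value,
    neg_log10_p = -log10(res$p_value),
    estimable = !mono,
    significant = !is.na(res$p_value) & res$p_value < thr
  )
  new_scan(out, method = "mma", alpha = alpha, n_tests = n_tests,
           threshold = thr,
           null_fit = c(sigma2_u = null$sigma2_u, sigma2_e = null$sigma2_e,
                        loglik = null$loglik))
}

#' Conditional single-SNP scan on one chromosome
#'
#' Re-runs the mixed-model SNP scan over one chromosome with the dosages
#' of one or more conditioning markers included as fixed covariates -- the
#' device used to ask whether a second signal survives once a first QTL is
#' in the model.  A tested SNP collinear with a conditioning marker is
#' flagged non-estimable.  An empty conditioning list reduces exactly to
#' [scan_mma()] on that chromosome.
#'
#' @inheritParams scan_mma
#' @param condition_on Character vector of conditioning SNP names.
#' @param chromosome Chromosome to scan.
#' @return A `pg_scan` tibble as in [scan_mma()].
#' @export
conditional_scan <- function(phenotypes, dosage, A, map, condition_on,
                             chromosome, alpha = 0.05, eig = NULL) {
  missing_cond <- setdiff(condition_on, colnames(dosage))
  if (length(missing_cond)) {
    stop("unknown conditioning markers: ",
         paste(missing_cond, collapse = ", "), call. = FALSE)
  }
  keep <- which(map$chrom == chromosome)
  if (length(keep) == 0) stop("no SNPs on chromosome ", chromosome,
                              call. = FALSE)
  sub <- dosage[, keep, drop = FALSE]
  if (length(condition_on) == 0) {
    return(scan_mma(phenotypes, sub, A, map[keep, ], alpha = alpha,
                    eig = eig))
  }
  al <- align_scan_inputs(phenotypes, sub, A, eig)
  n <- length(al$y)
  Cmat <- dosage[rownames(sub), condition_on, drop = FALSE]
  Ct <- crossprod(al$U, Cmat)
  Xnull <- cbind(al$Ot, Ct)
  null <- reml_1k(al$yt, Xnull, al$d)
  w <- 1 / (null$lambda * al$d + 1)

  sw <- sqrt(w)
  yw <- al$yt * sw
  Xw0 <- Xnull * sw
  p <- ncol(Xnull) + 1L
  res <- vapply(seq_len(ncol(al$Gt)), function(j) {
    Xw <- cbind(Xw0, al$Gt[, j] * sw)
    XtX <- crossprod(Xw)
    ch <- tryCatch(chol(XtX), error = function(e) NULL)
    if (is.null(ch)) return(c(NA_real_, NA, NA, NA))
    Xty <- crossprod(Xw, yw)
    cf <- backsolve(ch, forwardsolve(t(ch), Xty))
    rss <- sum(yw^2) - sum(Xty * cf)
    if (rss <= 0) return(c(NA_real_, NA, NA, NA))
    s2 <- rss / (n - p)
    ep <- c(rep(0, p - 1), 1)
    vb <- s2 * backsolve(ch, forwardsolve(t(ch), ep))[p]
    b <- cf[p]
    wald <- b^2 / vb
    c(b, sqrt(vb), wald, pchisq(wald, 1, lower.tail = FALSE))
  }, numeric(4))

  n_tests <- sum(!is.na(res[4, ]))
  thr <- bonferroni_threshold(alpha, max(n_tests, 1))
  out <- tibble::tibble(
    snp = colnames(sub), chrom = map$chrom[keep], pos_cM = map$pos_cM[keep],
    effect = res[1, ], se = res[2, ], statistic = res[3, ],
    p_value = res[4, ], neg_log10_p = -log10(res[4, ]),
    estimable = !is.na(res[4, ]),
    significant = !is.na(res[4, ]) & res[4, ] < thr
  )
  new_scan(out, method = "mma_conditional", alpha = alpha,
           n_tests = n_tests, threshold = thr,
           null_fit = c(sigma2_u = null$sigma2_u,
                        sigma2_e = null$sigma2_e, loglik = null$loglik))
}

#' Joint mixed-model fit of a detected marker set
#'
#' Fits all detected SNPs simultaneously as fixed effects in the polygenic
#' mixed model and reports, per marker, the allele substitution effect,
#' `-log10` Wald p-value and the percentage of phenotypic variance
#' explained, computed as `100 * var(x_j bhat_j) / var(y)` on the analysis
#' sample.  Collinear members are dropped with a warning.
#'
#' @inheritParams scan_mma
#' @param detected Character vector of detected SNP names.
#' @return Tibble with `snp`, `chrom`, `pos_cM`, `effect`, `neg_log10_p`
#'   and `var_explained_pct`; the attribute `total_var_explained_pct`
#'   holds the fitted set's joint value.
#' @export
joint_fit <- function(phenotypes, dosage, A, map, detected, eig = NULL) {
  if (length(detected) == 0) {
    out <- tibble::tibble(snp = character(), chrom = integer(),
                          pos_cM = numeric(), effect = numeric(),
                          neg_log10_p = numeric(),
                          var_explained_pct = numeric())
    attr(out, "total_var_explained_pct") <- 0
    return(out)
  }
  missing_d <- setdiff(detected, colnames(dosage))
  if (length(missing_d)) stop("unknown detected markers: ",
                              paste(missing_d, collapse = ", "),
                              call. = FALSE)
  al <- align_scan_inputs(phenotypes, dosage[, detected, drop = FALSE],
                          A, eig)
  G <- dosage[rownames(al$dosage), detected, drop = FALSE]
  qrg <- qr(cbind(1, G))
  if (qrg$rank < ncol(G) + 1) {
    keep_idx <- sort(setdiff(qrg$pivot[seq_len(qrg$rank)], 1L)) - 1L
    warning("dropping collinear markers: ",
            paste(setdiff(detected, detected[keep_idx]), collapse = ", "))
    detected <- detected[keep_idx]
    G <- G[, detected, drop = FALSE]
  }
  Gt <- crossprod(al$U, G)
  X <- cbind(al$Ot, Gt)
  fit <- reml_1k(al$yt, X, al$d)
  w <- 1 / (fit$lambda * al$d + 1)
  sw <- sqrt(w)
  Xw <- X * sw
  yw <- al$yt * sw
  XtX <- crossprod(Xw)
  ch <- chol(XtX)
  Xty <- crossprod(Xw, yw)
  cf <- backsolve(ch, forwardsolve(t(ch), Xty))[, 1]
  rss <- sum(yw^2) - sum(Xty * cf)
  p <- ncol(X)
  s2 <- rss / (length(al$y) - p)
  vb <- s2 * diag(chol2inv(ch))
  beta <- unname(cf[-1])
  se <- sqrt(vb[-1])
  wald <- (beta / se)^2
  vy <- var(al$y)
  ve <- unname(100 * apply(G, 2, var) * beta^2 / vy)
  idx <- match(detected, colnames(dosage))
  out <- tibble::tibble(
    snp = detected,
    chrom = map$chrom[idx], pos_cM = map$pos_cM[idx],
    effect = beta,
    neg_log10_p = -log10(pchisq(wald, 1, lower.tail = FALSE)),
    var_explained_pct = ve
  )
  fitted_g <- as.vector(G %*% beta)
  attr(out, "total_var_explained_pct") <- 100 * var(fitted_g) / vy
  out
}

# ---- internal scan helpers -------------------------------------------------

align_scan_inputs <- function(phenotypes, dosage, A, eig = NULL) {
  ids <- rownames(dosage)
  if (is.null(ids)) stop("dosage matrix needs id rownames", call. = FALSE)
  y <- phenotypes$value[match(ids, as.character(phenotypes$id))]
  if (anyNA(y)) stop("genotyped individuals without phenotype records",
                     call. = FALSE)
  if (is.null(eig)) {
    A2 <- kinship_submatrix(A, ids)
    eig <- eigen(A2, symmetric = TRUE)
  }
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  ones <- matrix(1, length(y), 1)
  list(y = y, d = d, U = U, yt = crossprod(U, y)[, 1],
       Ot = crossprod(U, ones), Gt = crossprod(U, dosage),
       dosage = dosage)
}

# vectorised Wald scan for X = [1, x_j], rotated model with diagonal
# weights w; returns one row per column of Gt
wald_scan_vec <- function(yt, Ot, Gt, w, n) {
  o <- Ot[, 1]
  S11 <- sum(w * o^2)
  S1y <- sum(w * o * yt)
  Syy <- sum(w * yt^2)
  S1g <- as.vector(crossprod(Gt, w * o))
  Sgy <- as.vector(crossprod(Gt, w * yt))
  Sgg <- as.vector(colSums(w * Gt^2))
  det <- S11 * Sgg - S1g^2
  det[det <= 0] <- NA
  beta <- (S11 * Sgy - S1g * S1y) / det
  beta0 <- (Sgg * S1y - S1g * Sgy) / det
  rss <- Syy - beta0 * S1y - beta * Sgy
  s2 <- rss / (n - 2)
  vb <- s2 * S11 / det
  wald <- beta^2 / vb
  data.frame(effect = beta, se = sqrt(vb), statistic = wald,
             p_value = pchisq(wald, 1, lower.tail = FALSE))
}

new_scan <- function(tbl, method, alpha, n_tests, threshold, null_fit) {
  structure(tbl, class = c("pg_scan", class(tbl)),
            method = method, alpha = alpha, n_tests = n_tests,
            threshold = threshold, null_fit = null_fit)
}
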