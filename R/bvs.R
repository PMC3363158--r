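#' Spike-and-slab prior for Bayesian variable selection
#'
#' Two-component normal mixture prior on SNP effects: a small fraction
#' `pi` of markers carries large effects (variance `sigma1^2`) and the rest
#' very small effects (variance `sigma0^2`); both variances are estimated
#' with scaled-inverse-chi-square priors.  The default scales spread an
#' assumed 30% of phenotypic variance over the `pi * M` large-effect SNPs
#' and 1% over the remainder; they are computed from the data at fit time
#' when left `NULL`.
#'
#' @param pi Prior inclusion probability (default 0.02: 2% of SNPs large).
#' @param df Prior degrees of freedom for both mixture variances.
#' @param scale_s0,scale_s1 Prior scales for the small/large effect
#'   variances (`NULL` = derive from the data).
#' @param df_resid,scale_se Residual variance prior (scale `NULL` = half
#'   the phenotypic variance).
#' @return An object of class `pg_bvs_prior`.
#' @export
bvs_prior <- function(pi = 0.02, df = 4, scale_s0 = NULL, scale_s1 = NULL,
                      df_resid = 4, scale_se = NULL) {
  stopifnot(pi > 0, pi < 1, df > 0, df_resid > 0)
  structure(list(pi = pi, df = df, scale_s0 = scale_s0,
                 scale_s1 = scale_s1, df_resid = df_resid,
                 scale_se = scale_se),
            class = "pg_bvs_prior")
}

#' Gibbs sampler for spike-and-slab SNP selection
#'
#' Fits all SNPs simultaneously under the two-component mixture prior of
#' [bvs_prior()] by single-site Gibbs sampling: each sweep redraws every
#' SNP's effect from its conditional normal, its mixture indicator from the
#' conditional Bernoulli comparing the two components' marginal
#' likelihoods, and (optionally) the three variances from their conjugate
#' scaled-inverse-chi-square conditionals.  The per-SNP posterior inclusion
#' probability (PIP) is the post-burn-in mean of the indicator.
#'
#' @param phenotypes Tibble with `id` and `value` columns.
#' @param dosage Dosage matrix (individuals x SNPs, rownames = ids).
#' @param map Optional map tibble aligned to the dosage columns; carried
#'   into the result for downstream calling.
#' @param prior A [bvs_prior()].
#' @param iterations,burn_in,thin Sampler schedule.
#' @param seed Integer seed (required; drives R's RNG).
#' @param update_variances,update_mu Set `FALSE` to hold the variances or
#'   the mean fixed (used for exact small-instance validation).
#' @param s0,s1,se Initial (or, when not updated, fixed) variance values;
#'   `NULL` = prior scales.
#' @param A Optional additive relationship matrix; when given, a
#'   pedigree polygenic effect `u ~ N(0, A sigma_u^2)` is sampled
#'   alongside the SNP effects (via the kinship eigenbasis).  By default
#'   no polygenic term is fitted: the markers themselves absorb the
#'   polygenic signal.
#'
#' @return An object of class `pg_pip`: a tibble with one row per SNP
#'   (`snp`, `chrom`, `pos_cM` when a map is given, `pip`,
#'   `post_mean_effect`) plus attributes `variances` (posterior means),
#'   `prior` and `settings`.
#' @export
gibbs_bvs <- function(phenotypes, dosage, map = NULL, prior = bvs_prior(),
                      iterations = 50000, burn_in = 10000, thin = 10,
                      seed, update_variances = TRUE, update_mu = TRUE,
                      s0 = NULL, s1 = NULL, se = NULL, A = NULL) {
  stopifnot(inherits(prior, "pg_bvs_prior"), iterations > burn_in)
  y <- phenotypes$value[match(rownames(dosage), as.character(phenotypes$id))]
  if (anyNA(y)) stop("dosage rows without phenotype records", call. = FALSE)
  if (any(!is.finite(y))) stop("non-finite phenotype values", call. = FALSE)
  M <- ncol(dosage)
  vy <- var(y)
  colvar <- apply(dosage, 2, var)
  if (all(colvar == 0)) warning("all SNPs are monomorphic")
  vbar <- if (any(colvar > 0)) mean(colvar[colvar > 0]) else 1
  scale_s1 <- prior$scale_s1 %||% (0.30 * vy / (prior$pi * M * vbar))
  scale_s0 <- prior$scale_s0 %||% (0.01 * vy / ((1 - prior$pi) * M * vbar))
  scale_se <- prior$scale_se %||% (0.5 * vy)

  U <- NULL; dvals <- NULL
  if (!is.null(A)) {
    eig <- eigen(kinship_submatrix(A, rownames(dosage)), symmetric = TRUE)
    U <- eig$vectors
    dvals <- pmax(eig$values, 0)
  }
  set.seed(seed)
  fit <- bvs_gibbs_cpp(as.numeric(y), as.matrix(dosage) * 1.0, prior$pi,
                       prior$df, scale_s0, scale_s1,
                       prior$df_resid, scale_se,
                       as.integer(iterations), as.integer(burn_in),
                       as.integer(thin),
                       update_variances, update_mu,
                       s0 %||% scale_s0, s1 %||% scale_s1, se %||% scale_se,
                       U_ = U, d_ = dvals,
                       su_scale = 0.3 * vy, su_df = prior$df)

  out <- tibble::tibble(
    snp = colnames(dosage) %||% paste0("snp", seq_len(M)),
    pip = fit$pip,
    post_mean_effect = fit$post_mean_effect
  )
  if (!is.null(map)) {
    out <- dplyr::bind_cols(map[, c("chrom", "pos_cM")], out) |>
      dplyr::relocate("snp")
  }
  structure(out, class = c("pg_pip", class(out)),
            variances = c(sigma2_0 = fit$sigma2_0, sigma2_1 = fit$sigma2_1,
                          sigma2_e = fit$sigma2_e, sigma2_u = fit$sigma2_u,
                          mu = fit$mu),
            prior = prior,
            settings = list(iterations = iterations, burn_in = burn_in,
                            thin = thin, seed = seed,
                            kept_samples = fit$kept_samples))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bayes factor implied by a posterior inclusion probability
#'
#' Posterior odds of inclusion divided by the prior odds:
#' `BF = [pip / (1 - pip)] / [pi / (1 - pi)]`.  A PIP of 0.10 under the
#' default 2% prior corresponds to a Bayes factor of about 5.4.
#'
#' @param pip Posterior inclusion probability, strictly in (0, 1).
#' @param prior_pi Prior inclusion probability, strictly in (0, 1).
#' @return The Bayes factor.
#' @export
#' @examples
#' pip_to_bayes_factor(0.10, 0.02)
pip_to_bayes_factor <- function(pip, prior_pi) {
  if (any(pip <= 0 | pip >= 1) || any(prior_pi <= 0 | prior_pi >= 1)) {
    stop("pip and prior_pi must lie strictly inside (0, 1)", call. = FALSE)
  }
  (pip / (1 - pip)) / (prior_pi / (1 - prior_pi))
}

#' Call QTL from a PIP track with local-maximum pruning
#'
#' Candidate SNPs are those with `pip > threshold`.  Because linkage
#' disequilibrium smears posterior probability over adjacent markers, a
#' run of candidates whose successive gaps are below `prune_window_cM`
#' (same chromosome) is collapsed to its maximum-PIP SNP (ties broken to
#' the lowest position).
#'
#' @param track A `pg_pip` result from [gibbs_bvs()]; must carry `chrom`
#'   and `pos_cM` columns (fit with a map).
#' @param threshold PIP calling threshold in (0, 1).
#' @param prune_window_cM Gap below which adjacent candidates merge.
#' @return Tibble of calls: `snp`, `chrom`, `pos_cM`, `pip`,
#'   `post_mean_effect`, `bayes_factor`.
#' @export
call_qtl <- function(track, threshold = 0.10, prune_window_cM = 5) {
  stopifnot(threshold > 0, threshold < 1)
  if (!all(c("chrom", "pos_cM") %in% names(track))) {
    stop("track has no positions; fit gibbs_bvs() with a map", call. = FALSE)
  }
  prior <- attr(track, "prior")
  cand <- track |>
    dplyr::filter(.data$pip > threshold) |>
    dplyr::arrange(.data$chrom, .data$pos_cM)
  if (nrow(cand) == 0) {
    cand$bayes_factor <- numeric(0)
    return(cand)
  }
  gap_break <- c(TRUE, diff(cand$pos_cM) >= prune_window_cM |
                   diff(cand$chrom) != 0)
  cand |>
    dplyr::mutate(cluster = cumsum(gap_break)) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::slice(which.max(.data$pip)) |>
    dplyr::ungroup() |>
    dplyr::select(-"cluster") |>
    dplyr::mutate(bayes_factor = pip_to_bayes_factor(
      pmin(.data$pip, 1 - 1e-12), prior$pi))
}
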