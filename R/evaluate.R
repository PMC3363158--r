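#' Collapse a scan to its QTL call set
#'
#' Turns a `pg_scan` result into the one-position-per-region call set the
#' evaluation layer scores: runs of consecutive significant markers or
#' windows (same chromosome, no non-significant entry between) are merged
#' and each run is represented by its most significant entry.
#'
#' @param scan A `pg_scan` tibble (from [scan_mma()], [scan_rhm()] or
#'   [scan_genmix()]).
#' @return Tibble of calls: `chrom`, `pos_cM`, `statistic`, `p_value`.
#' @export
calls_from_scan <- function(scan) {
  sig <- which(!is.na(scan$significant) & scan$significant)
  if (length(sig) == 0) {
    return(tibble::tibble(chrom = integer(), pos_cM = numeric(),
                          statistic = numeric(), p_value = numeric()))
  }
  run <- cumsum(c(TRUE, diff(sig) != 1L |
                    diff(scan$chrom[sig]) != 0L))
  scan[sig, ] |>
    dplyr::mutate(run = run) |>
    dplyr::group_by(run) |>
    dplyr::slice(which.min(.data$p_value)) |>
    dplyr::ungroup() |>
    dplyr::select("chrom", "pos_cM", "statistic", "p_value")
}

#' Match QTL calls to simulated truth
#'
#' Greedy one-to-one nearest-first matching within chromosomes: candidate
#' (truth, call) pairs at distance below the tolerance are taken in order
#' of ascending distance (ties towards the lower call position); each true
#' QTL takes at most one call and each call matches at most one QTL.
#' Unmatched calls are false positives.
#'
#' @param calls Tibble with `chrom` and `pos_cM` (one row per call).
#' @param truth Truth tibble with `chrom` and `pos_cM`.
#' @param tolerance_cM Maximum distance for a call to identify a QTL.
#' @return A list: `truth` (input truth plus `detected`, `call_pos`,
#'   `abs_error`) and `calls` (input calls plus `matched`,
#'   `matched_qtl`).
#' @export
match_qtl <- function(calls, truth, tolerance_cM = 10) {
  stopifnot(tolerance_cM > 0)
  nt <- nrow(truth); nc <- nrow(calls)
  pairs <- tidyr::expand_grid(ti = seq_len(nt), ci = seq_len(nc))
  if (nrow(pairs)) {
    pairs <- pairs |>
      dplyr::filter(truth$chrom[.data$ti] == calls$chrom[.data$ci]) |>
      dplyr::mutate(dist = abs(truth$pos_cM[.data$ti] -
                                 calls$pos_cM[.data$ci]),
                    cpos = calls$pos_cM[.data$ci]) |>
      dplyr::filter(.data$dist <= tolerance_cM) |>
      dplyr::arrange(.data$dist, .data$cpos)
  }
  t_match <- rep(NA_integer_, nt)
  c_match <- rep(NA_integer_, nc)
  for (i in seq_len(nrow(pairs))) {
    ti <- pairs$ti[i]; ci <- pairs$ci[i]
    if (is.na(t_match[ti]) && is.na(c_match[ci])) {
      t_match[ti] <- ci
      c_match[ci] <- ti
    }
  }
  truth_out <- truth |>
    dplyr::mutate(detected = !is.na(t_match),
                  call_pos = ifelse(is.na(t_match), NA_real_,
                                    calls$pos_cM[t_match]),
                  abs_error = abs(.data$call_pos - .data$pos_cM))
  calls_out <- calls |>
    dplyr::mutate(matched = !is.na(c_match), matched_qtl = c_match)
  list(truth = truth_out, calls = calls_out)
}

#' Score one method's calls against the truth
#'
#' Counts detected QTL (calls within the tolerance of a true position,
#' matched one-to-one), false positives (unmatched calls) and the mapping
#' precision, defined as the mean absolute cM difference between each
#' detected QTL's true and called positions.
#'
#' @param calls Call tibble (`chrom`, `pos_cM`).
#' @param truth Truth tibble.
#' @param tolerance_cM Identification tolerance (10 cM by default).
#' @param method Optional method name carried into the report.
#' @return One-row tibble: `method`, `n_true`, `n_calls`, `detected`,
#'   `missed`, `false_positives`, `precision_cM`.
#' @export
score_method <- function(calls, truth, tolerance_cM = 10,
                         method = "method") {
  m <- match_qtl(calls, truth, tolerance_cM)
  det <- sum(m$truth$detected)
  tibble::tibble(
    method = method,
    n_true = nrow(truth),
    n_calls = nrow(calls),
    detected = det,
    missed = nrow(truth) - det,
    false_positives = sum(!m$calls$matched),
    precision_cM = if (det > 0) mean(m$truth$abs_error, na.rm = TRUE)
                   else NA_real_
  )
}

#' Compare several methods' call sets
#'
#' Builds the cross-method comparison: one summary row per method
#' ([score_method()]) and a long per-call / per-truth table ready for
#' plotting (true positions, calls coloured by matched / false-positive
#' status per method).
#'
#' @param call_sets Named list of call tibbles (one per method).
#' @param truth Truth tibble.
#' @param tolerance_cM Identification tolerance.
#' @return An object of class `pg_evaluation`: list with `summary`
#'   (per-method scores), `detail` (per-method truth matching) and
#'   `positions` (plot-ready long tibble).
#' @export
compare_methods <- function(call_sets, truth, tolerance_cM = 10) {
  stopifnot(length(call_sets) >= 1)
  if (is.null(names(call_sets))) {
    names(call_sets) <- paste0("method", seq_along(call_sets))
  }
  summaries <- list(); details <- list(); pos <- list()
  for (m in names(call_sets)) {
    mm <- match_qtl(call_sets[[m]], truth, tolerance_cM)
    summaries[[m]] <- score_method(call_sets[[m]], truth, tolerance_cM,
                                   method = m)
    details[[m]] <- dplyr::mutate(mm$truth, method = m, .before = 1)
    pos[[m]] <- tibble::tibble(
      method = m,
      chrom = mm$calls$chrom,
      pos_cM = mm$calls$pos_cM,
      status = ifelse(mm$calls$matched, "detected", "false_positive")
    )
  }
  structure(list(
    summary = dplyr::bind_rows(summaries),
    detail = dplyr::bind_rows(details),
    positions = dplyr::bind_rows(pos),
    truth = truth, tolerance_cM = tolerance_cM
  ), class = "pg_evaluation")
}

#' @export
print.pg_evaluation <- function(x, ...) {
  cat("QTL mapping evaluation (tolerance ", x$tolerance_cM, " cM):\n",
      sep = "")
  print(x$summary)
  invisible(x)
}

#' Run the full simulate-scan-evaluate pipeline
#'
#' Simulates a study with [simulate_qtlmas()], runs the four mapping
#' methods and scores them against the simulated truth.  Intended for
#' end-to-end experiments at reduced scale; the genome-wide default
#' configuration takes substantially longer than the scaled-down examples
#' in the vignette.
#'
#' @param seed Study seed.
#' @param alpha Experiment-wise significance level for the frequentist
#'   scans.
#' @param pip_threshold,prune_window_cM BVS calling parameters.
#' @param bvs_iterations,bvs_burn_in BVS sampler schedule.
#' @param tolerance_cM Evaluation tolerance.
#' @param ... Passed to [simulate_qtlmas()].
#' @return List with `sim`, the four scan objects, `calls` and
#'   `evaluation`.
#' @export
run_qtlmas_study <- function(seed, alpha = 0.05, pip_threshold = 0.10,
                             prune_window_cM = 5, bvs_iterations = 5000,
                             bvs_burn_in = 1000, tolerance_cM = 10, ...) {
  sim <- simulate_qtlmas(seed, ...)
  A <- additive_relationship(sim$pedigree)
  phased <- phased_genotypes(sim)
  dosage <- dosage_matrix(sim)
  eig <- eigen(kinship_submatrix(A, rownames(dosage)), symmetric = TRUE)

  mma <- scan_mma(sim$phenotypes, dosage, A, sim$map, alpha = alpha,
                  eig = eig)
  rhm <- scan_rhm(sim$phenotypes, phased, A, sim$map, alpha = alpha,
                  eig = eig)
  genmix <- scan_genmix(sim$phenotypes, phased, A, sim$map, alpha = alpha,
                        eig = eig)
  bvs <- gibbs_bvs(sim$phenotypes, dosage, map = sim$map,
                   iterations = bvs_iterations, burn_in = bvs_burn_in,
                   seed = seed)
  bvs_calls <- call_qtl(bvs, threshold = pip_threshold,
                        prune_window_cM = prune_window_cM)
  calls <- list(
    MMA = calls_from_scan(mma),
    RHM = calls_from_scan(rhm),
    GENMIX = calls_from_scan(genmix),
    BVS = bvs_calls[, c("chrom", "pos_cM")]
  )
  list(sim = sim, mma = mma, rhm = rhm, genmix = genmix, bvs = bvs,
       calls = calls,
       evaluation = compare_methods(calls, sim$truth, tolerance_cM))
}
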