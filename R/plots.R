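#' Manhattan-style plot of a scan result
#'
#' Plots `-log10(p)` against genetic position, faceted by chromosome, with
#' the Bonferroni per-test threshold as a dashed line.
#'
#' @param object A `pg_scan` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pg_scan <- function(object, ...) {
  thr <- attr(object, "threshold")
  ggplot2::ggplot(dplyr::filter(object, !is.na(.data$p_value)),
                  ggplot2::aes(x = .data$pos_cM, y = .data$neg_log10_p)) +
    ggplot2::geom_point(size = 0.4, colour = "grey30") +
    ggplot2::geom_hline(yintercept = -log10(thr), linetype = "dashed",
                        colour = "red") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (cM)", y = expression(-log[10](p)),
                  title = paste0(attr(object, "method"), " scan")) +
    ggplot2::theme_minimal()
}

#' Posterior inclusion probability track plot
#'
#' @param object A `pg_pip` result from [gibbs_bvs()] fitted with a map.
#' @param threshold Calling threshold drawn as a dashed line.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pg_pip <- function(object, threshold = 0.10, ...) {
  if (!all(c("chrom", "pos_cM") %in% names(object))) {
    stop("PIP track has no positions; fit gibbs_bvs() with a map",
         call. = FALSE)
  }
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$pos_cM, y = .data$pip)) +
    ggplot2::geom_point(size = 0.4, colour = "grey30") +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "red") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (cM)", y = "posterior inclusion prob.") +
    ggplot2::theme_minimal()
}

#' Comparison plot of simulated and detected QTL positions
#'
#' Mirrors the classic benchmark figure: true QTL positions as diamonds,
#' each method's calls as points coloured by detected / false-positive
#' status, per chromosome.
#'
#' @param object A `pg_evaluation` from [compare_methods()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pg_evaluation <- function(object, ...) {
  truth <- dplyr::mutate(object$truth, method = "truth")
  ggplot2::ggplot() +
    ggplot2::geom_point(
      data = object$positions,
      ggplot2::aes(x = .data$pos_cM, y = .data$method,
                   colour = .data$status), shape = 16, size = 2) +
    ggplot2::geom_point(
      data = truth,
      ggplot2::aes(x = .data$pos_cM, y = .data$method),
      shape = 18, size = 3, colour = "red") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$chrom)) +
    ggplot2::scale_colour_manual(values = c(detected = "steelblue",
                                            false_positive = "grey50")) +
    ggplot2::labs(x = "position (cM)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method generics::tidy
tidy.pg_scan <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @exportS3Method generics::glance
glance.pg_scan <- function(x, ...) {
  tibble::tibble(
    method = attr(x, "method"),
    n_tests = attr(x, "n_tests"),
    alpha = attr(x, "alpha"),
    threshold = attr(x, "threshold"),
    n_significant = sum(x$significant, na.rm = TRUE),
    min_p = min(x$p_value, na.rm = TRUE)
  )
}

#' @exportS3Method generics::glance
glance.pg_pip <- function(x, ...) {
  v <- attr(x, "variances")
  s <- attr(x, "settings")
  tibble::tibble(
    n_snps = nrow(x), max_pip = max(x$pip),
    sigma2_0 = v[["sigma2_0"]], sigma2_1 = v[["sigma2_1"]],
    sigma2_e = v[["sigma2_e"]],
    iterations = s$iterations, kept_samples = s$kept_samples
  )
}
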