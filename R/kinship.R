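#' Additive (numerator) relationship matrix from a pedigree
#'
#' Computes Wright's numerator relationship matrix A by the tabular method:
#' founders have a self-relationship of 1 and are mutually unrelated; for an
#' offspring o with parents s and d, `a(i, o) = (a(i, s) + a(i, d)) / 2` for
#' any earlier individual i, and `a(o, o) = 1 + a(s, d) / 2`.  A is the
#' covariance kernel of the polygenic random effect in all the mixed models
#' of this package.
#'
#' @param pedigree A pedigree tibble as returned by [build_pedigree()];
#'   parents must appear before their offspring.
#'
#' @return A dense symmetric matrix with individual ids as dimnames.
#' @export
#' @examples
#' A <- additive_relationship(build_pedigree(1, 1, 2, 2))
#' A["3", "4"]  # full sibs: 0.5
additive_relationship <- function(pedigree) {
  check_pedigree_order(pedigree)
  n <- nrow(pedigree)
  sp <- match(pedigree$sire, pedigree$id, nomatch = 0L)
  dp <- match(pedigree$dam,  pedigree$id, nomatch = 0L)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- sp[i]; d <- dp[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (s > 0L) row <- row + A[j, s]
      if (d > 0L) row <- row + A[j, d]
      row <- row / 2
      A[j, i] <- row
      A[i, j] <- row
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) A[s, d] / 2 else 0
  }
  dimnames(A) <- list(pedigree$id, pedigree$id)
  A
}

#' Extract a sub-kinship-matrix for a set of individuals
#'
#' @param K Kinship matrix with id dimnames (see [additive_relationship()]).
#' @param ids Ids to keep, in the requested order.
#'
#' @return The `length(ids)` square submatrix.
#' @export
kinship_submatrix <- function(K, ids) {
  idx <- match(as.character(ids), rownames(K))
  if (anyNA(idx)) {
    stop("unknown ids in kinship matrix: ",
         paste(utils::head(ids[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  K[idx, idx, drop = FALSE]
}

#' Write the lower triangle of a kinship matrix as TSV
#'
#' Emits rows (id1, id2, a) for `a != 0` entries of the lower triangle,
#' for inspection with command-line tools.
#'
#' @param K Kinship matrix with id dimnames.
#' @param path Output file.
#' @export
write_kinship_tsv <- function(K, path) {
  lt <- which(lower.tri(K, diag = TRUE) & K != 0, arr.ind = TRUE)
  readr::write_tsv(
    tibble::tibble(id1 = rownames(K)[lt[, 1]],
                   id2 = colnames(K)[lt[, 2]],
                   a = K[lt]),
    path
  )
  invisible(path)
}
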