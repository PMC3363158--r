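#' Four-gamete compatibility of two bi-allelic sites
#'
#' Two sites are consistent with a single genealogy without recurrent
#' mutation or recombination iff at most three of the four possible
#' gamete types (00, 01, 10, 11) occur among the haplotypes.
#'
#' @param col_a,col_b Binary vectors of equal length.
#' @return `TRUE` iff the sites are compatible.
#' @export
four_gamete_compatible <- function(col_a, col_b) {
  stopifnot(length(col_a) == length(col_b), length(col_a) >= 1)
  length(unique(2L * col_a + col_b)) <= 3L
}

#' Widest four-gamete-compatible interval around a focal site
#'
#' Greedily grows a contiguous interval around the focal site, trying the
#' left neighbour first and then the right on every pass, and accepting a
#' site only while every pair of sites inside the interval stays
#' four-gamete compatible.  The result is maximal in the sense that
#' neither end can be extended by one more site (the greedy interval need
#' not be the globally widest compatible one).
#'
#' @param H Binary haplotype matrix (haplotypes x sites).
#' @param focal Focal site (column) index.
#' @return Integer vector `c(start, end)` of column indices.
#' @export
widest_compatible_region <- function(H, focal) {
  m <- ncol(H)
  stopifnot(focal >= 1, focal <= m)
  compat_with_all <- function(cand, lo, hi) {
    x <- H[, cand]
    for (j in lo:hi) {
      if (length(unique(2L * x + H[, j])) > 3L) return(FALSE)
    }
    TRUE
  }
  lo <- hi <- focal
  repeat {
    moved <- FALSE
    if (lo > 1L && compat_with_all(lo - 1L, lo, hi)) {
      lo <- lo - 1L; moved <- TRUE
    }
    if (hi < m && compat_with_all(hi + 1L, lo, hi)) {
      hi <- hi + 1L; moved <- TRUE
    }
    if (!moved) break
  }
  c(start = lo, end = hi)
}

#' Perfect phylogeny over a compatible haplotype region
#'
#' Builds the local genealogy of a set of haplotypes over an interval in
#' which every pair of sites passes the four-gamete condition.  The
#' majority allele at each site is treated as ancestral (allele 0 on an
#' exact 50/50 split); derived-carrier sets are then laminar, and the tree
#' is built by inclusion ordering (sites sorted by derived-carrier-set
#' size), merging duplicate columns into a single edge.  Haplotypes
#' identical across the interval form one leaf group.  Multifurcations are
#' resolved into a bifurcating tree with zero-length internal edges, in
#' site order.
#'
#' @param H Binary haplotype matrix (haplotypes x sites) over the
#'   interval; all site pairs must be compatible.
#' @param site_ids Optional identifiers for the columns (for annotation).
#' @return An object of class `pg_local_tree`: a list with `root` (nested
#'   node list: `groups`, `children`, `sites`, `zero_length`),
#'   `leaf_groups` (list of haplotype index vectors), `group_of` (leaf
#'   group per haplotype) and `n_hap`.
#' @export
build_perfect_phylogeny <- function(H, site_ids = NULL) {
  H <- as.matrix(H)
  n_hap <- nrow(H)
  if (is.null(site_ids)) site_ids <- seq_len(ncol(H))

  key <- apply(H, 1, paste, collapse = "")
  ukey <- unique(key)
  group_of <- match(key, ukey)
  n_grp <- length(ukey)
  leaf_groups <- unname(split(seq_len(n_hap), group_of))
  grp_size <- lengths(leaf_groups)

  # derived carrier sets per site, over leaf groups
  rep_rows <- match(seq_len(n_grp), group_of)  # one haplotype per group
  carriers <- list(); carrier_sites <- list()
  seen <- character()
  for (j in seq_len(ncol(H))) {
    n1 <- sum(H[, j])
    if (n1 == 0 || n1 == n_hap) next
    derived <- if (n1 * 2L > n_hap) 0L else 1L  # tie: allele 1 derived
    cg <- which(H[rep_rows, j] == derived)
    k <- paste(cg, collapse = ",")
    hit <- match(k, seen)
    if (is.na(hit)) {
      seen <- c(seen, k)
      carriers[[length(carriers) + 1L]] <- cg
      carrier_sites[[length(carriers)]] <- site_ids[j]
    } else {
      carrier_sites[[hit]] <- c(carrier_sites[[hit]], site_ids[j])
    }
  }
  # drop the full set (possible when a tie made every haplotype derived)
  full <- vapply(carriers, function(s) length(s) == n_grp, TRUE)
  carriers <- carriers[!full]; carrier_sites <- carrier_sites[!full]

  hap_count <- vapply(carriers, function(s) sum(grp_size[s]), 0)
  ord <- order(-hap_count, vapply(carrier_sites, min, 0))
  carriers <- carriers[ord]; carrier_sites <- carrier_sites[ord]

  node <- function(groups, sites = NULL, zero_length = FALSE) {
    list(groups = sort(groups), children = list(), sites = sites,
         zero_length = zero_length)
  }
  root <- node(seq_len(n_grp))

  insert <- function(nd, child) {
    # descend to the deepest node whose group set contains the child's
    for (i in seq_along(nd$children)) {
      if (all(child$groups %in% nd$children[[i]]$groups)) {
        nd$children[[i]] <- insert(nd$children[[i]], child)
        return(nd)
      }
    }
    nd$children[[length(nd$children) + 1L]] <- child
    nd
  }
  for (i in seq_along(carriers)) {
    if (length(carriers[[i]]) == n_grp) next
    root <- insert(root, node(carriers[[i]], sites = carrier_sites[[i]]))
  }
  # attach leaf groups not already isolated by an edge
  attach_leaves <- function(nd) {
    covered <- unlist(lapply(nd$children, `[[`, "groups"))
    for (g in setdiff(nd$groups, covered)) {
      if (length(nd$groups) > 1L || length(nd$children) > 0L) {
        nd$children[[length(nd$children) + 1L]] <- node(g)
      }
    }
    nd$children <- lapply(nd$children, attach_leaves)
    nd
  }
  root <- attach_leaves(root)
  # collapse single-child chains (an edge isolating exactly one subtree)
  collapse <- function(nd) {
    nd$children <- lapply(nd$children, collapse)
    if (length(nd$children) == 1L) {
      ch <- nd$children[[1L]]
      ch$sites <- c(nd$sites, ch$sites)
      return(ch)
    }
    nd
  }
  root <- collapse(root)
  # binarise multifurcations with zero-length edges, in child (site) order
  binarise <- function(nd) {
    nd$children <- lapply(nd$children, binarise)
    while (length(nd$children) > 2L) {
      k <- length(nd$children)
      merged <- node(c(nd$children[[k - 1L]]$groups,
                       nd$children[[k]]$groups), zero_length = TRUE)
      merged$children <- nd$children[c(k - 1L, k)]
      nd$children <- c(nd$children[seq_len(k - 2L)], list(merged))
    }
    nd
  }
  root <- binarise(root)

  structure(list(root = root, leaf_groups = leaf_groups,
                 group_of = group_of, n_hap = n_hap),
            class = "pg_local_tree")
}

#' @export
print.pg_local_tree <- function(x, ...) {
  cat("Local genealogy:", x$n_hap, "haplotypes in",
      length(x$leaf_groups), "leaf groups\n")
  invisible(x)
}

#' Newick string of a local tree (leaf groups as labels)
#'
#' @param tree A `pg_local_tree`.
#' @return A newick string; leaf-group labels are `g<id>` with the member
#'   haplotype indices appended after a colon comment-free convention
#'   `g3_n5` (group 3, five haplotypes).
#' @export
tree_newick <- function(tree) {
  sizes <- lengths(tree$leaf_groups)
  rec <- function(nd) {
    if (length(nd$children) == 0L) {
      g <- nd$groups
      return(paste0("g", g, "_n", sizes[g]))
    }
    paste0("(", paste(vapply(nd$children, rec, ""), collapse = ","), ")")
  }
  paste0(rec(tree$root), ";")
}

#' Enumerate haplotype clusterings from tree splits
#'
#' Cutting the genealogy at its root yields one partition into two
#' clusters; cutting at any lower node yields three clusters (everything
#' above the cut, plus the node's two branches).  Following the
#' three-level scheme, the root gives one 2-cluster partition, the root's
#' two children (when internal) give up to two 3-cluster partitions, and
#' the four grandchildren up to four more -- at most seven clusterings
#' per marker.
#'
#' @param tree A `pg_local_tree` from [build_perfect_phylogeny()].
#' @param levels How many levels to cut (1 to 3).
#' @return A list of clusterings, each a list with `id`, `level` and
#'   `labels` (integer cluster label in 1..3 per haplotype; the cluster
#'   above the cut point is label 1).  A degenerate tree with fewer than
#'   two leaf groups returns an empty list with a warning.
#' @export
enumerate_clusterings <- function(tree, levels = 3) {
  stopifnot(levels >= 1)
  if (length(tree$leaf_groups) < 2L) {
    warning("degenerate tree: fewer than two leaf groups")
    return(list())
  }
  grp_label <- function(sets) {
    lab_of_grp <- integer(length(tree$leaf_groups))
    for (k in seq_along(sets)) lab_of_grp[sets[[k]]] <- k
    lab_of_grp[tree$group_of]
  }
  out <- list()
  root <- tree$root
  out[[1]] <- list(id = "top", level = 1L,
                   labels = grp_label(list(root$children[[1]]$groups,
                                           root$children[[2]]$groups)))
  if (levels >= 2) {
    lvl2 <- root$children
    for (i in seq_along(lvl2)) {
      nd <- lvl2[[i]]
      if (length(nd$children) == 2L) {
        out[[length(out) + 1L]] <- list(
          id = paste0("L2.", i), level = 2L,
          labels = grp_label(list(setdiff(root$groups, nd$groups),
                                  nd$children[[1]]$groups,
                                  nd$children[[2]]$groups)))
      }
    }
  }
  if (levels >= 3) {
    gc_idx <- 0L
    for (ch in root$children) {
      for (nd in ch$children) {
        gc_idx <- gc_idx + 1L
        if (length(nd$children) == 2L) {
          out[[length(out) + 1L]] <- list(
            id = paste0("L3.", gc_idx), level = 3L,
            labels = grp_label(list(setdiff(root$groups, nd$groups),
                                    nd$children[[1]]$groups,
                                    nd$children[[2]]$groups)))
        }
      }
    }
  }
  out
}
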