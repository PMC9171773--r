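#' Z-score an abundance matrix by taxon
#'
#' Centers and scales each taxon column to mean 0 and sample SD 1 (n - 1
#' denominator), so abundances become enrichment scores comparable across
#' channels with very different dynamic ranges. Zero-variance columns map
#' to all-zeros and are flagged in attribute `"zero_variance"`.
#'
#' @param m Numeric matrix, rows = crypts, columns = taxa (>= 2 rows).
#' @return Z-scored matrix with the same dimnames.
#' @export
zscore_by_taxon <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("Z-scoring needs at least 2 rows (SD undefined)")
  mu <- colMeans(m)
  sd <- apply(m, 2L, stats::sd)
  zero <- sd == 0 | !is.finite(sd)
  sd[zero] <- 1
  z <- sweep(sweep(m, 2L, mu, "-"), 2L, sd, "/")
  z[, zero] <- 0
  attr(z, "zero_variance") <- colnames(m)[zero]
  z
}

#' Cosine distance between two vectors
#'
#' `1 - cos(u, v)`, in `[0, 2]`. By convention two zero vectors are at
#' distance 0 from each other and at distance 1 from anything else (a
#' warning flags the degenerate case).
#'
#' @param u,v Numeric vectors of equal length.
#' @return Scalar in `[0, 2]`.
#' @export
cosine_distance <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    warning("cosine distance with zero vector(s); using the 0/1 convention")
    return(if (nu == 0 && nv == 0) 0 else 1)
  }
  1 - sum(u * v) / (nu * nv)
}

# full pairwise cosine distance matrix; zero rows handled by convention
cosine_dist_matrix <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  zero <- nrm == 0
  nrm[zero] <- 1
  s <- (m / nrm) %*% t(m / nrm)
  d <- 1 - s
  d[d < 0] <- 0
  if (any(zero)) {
    d[zero, ] <- 1; d[, zero] <- 1
    d[zero, zero] <- 0
  }
  diag(d) <- 0
  d
}

#' Hierarchical clustering of crypts or taxa by cosine similarity
#'
#' Agglomerative clustering (average linkage by default) on the cosine
#' distance matrix of the Z-scored abundance matrix; the same routine
#' clusters either the crypt axis or the taxon axis, the two independent
#' orderings of a community heat map. Merges are deterministic:
#' `stats::hclust` breaks exact ties toward the earlier-formed/lower-index
#' agglomeration.
#'
#' @param z Z-scored matrix (crypts x taxa).
#' @param axis `"crypts"` (rows) or `"taxa"` (columns).
#' @param method Linkage: `"average"` (default), `"complete"` or `"ward.D2"`.
#' @return An `hclust` tree with attribute `"cosine_dist"` (the distance
#'   matrix used).
#' @export
hca <- function(z, axis = c("crypts", "taxa"), method = "average") {
  axis <- match.arg(axis)
  m <- if (axis == "crypts") z else t(z)
  if (nrow(m) < 2L) stop("hca needs at least 2 items on the chosen axis")
  d <- cosine_dist_matrix(m)
  rownames(d) <- colnames(d) <- rownames(m)
  tree <- stats::hclust(stats::as.dist(d), method = method)
  attr(tree, "cosine_dist") <- d
  tree
}

#' Cut an HCA tree into k community types
#'
#' Cuts the tree at the height giving exactly `k` groups and assigns labels
#' `A`, `B`, ... ordered by cluster size descending (ties toward the
#' cluster containing the smallest row index), mirroring the six most
#' prominent branches rule with k = 6.
#'
#' Crypts whose Z-scored profile is exactly zero (every taxon at its column
#' mean) have no cosine direction; when the Z matrix is supplied they are
#' reassigned post hoc to the type with the nearest (Euclidean) centroid
#' and flagged in the `reassigned` column.
#'
#' @param tree `hclust` tree from [hca()].
#' @param k Number of types (1 <= k <= n).
#' @param crypt_ids Optional ids for the clustered rows.
#' @param z Optional Z-scored matrix used to detect and reassign zero rows.
#' @return A list of class `type_assignment`: `labels` (data.frame
#'   `crypt_id`, `type`, `reassigned`), `k`, `tree`.
#' @export
cut_tree <- function(tree, k = 6L, crypt_ids = tree$labels, z = NULL) {
  n <- length(tree$order)
  if (k > n) stop("k (", k, ") exceeds number of items (", n, ")")
  if (k < 1L) stop("k must be >= 1")
  grp <- stats::cutree(tree, k = k)
  if (is.null(crypt_ids)) crypt_ids <- seq_len(n)
  sizes <- tabulate(grp, nbins = k)
  first <- vapply(seq_len(k), function(g) min(which(grp == g)), integer(1))
  ord <- order(-sizes, first)
  lab <- make.unique(c(LETTERS, paste0("Z", seq_len(max(0, k - 26)))))[seq_len(k)]
  relab <- character(k); relab[ord] <- lab
  type <- relab[grp]
  reassigned <- rep(FALSE, n)
  if (!is.null(z)) {
    zr <- rowSums(as.matrix(z)^2) == 0
    if (any(zr) && !all(zr)) {
      cents <- vapply(seq_len(k), function(g) {
        rows <- which(grp == g & !zr)
        if (!length(rows)) rep(NA_real_, ncol(z))
        else colMeans(z[rows, , drop = FALSE])
      }, numeric(ncol(z)))
      for (i in which(zr)) {
        d2 <- colSums((cents - z[i, ])^2)
        g <- which.min(d2)
        type[i] <- relab[g]
        reassigned[i] <- TRUE
      }
    }
  }
  structure(list(labels = data.frame(crypt_id = crypt_ids,
                                     type = type, reassigned = reassigned,
                                     stringsAsFactors = FALSE),
                 k = k, tree = tree),
            class = "type_assignment")
}

#' @export
print.type_assignment <- function(x, ...) {
  cat("type_assignment: k =", x$k, "\n")
  print(table(x$labels$type))
  invisible(x)
}

#' Silhouette scores of a community-type assignment
#'
#' Standard silhouette with cosine distance: for crypt i,
#' `s(i) = (b - a) / max(a, b)` where `a` is the mean distance to its own
#' type and `b` the smallest mean distance to another type. Singleton
#' clusters score 0; when `a = b = 0` (identical points) the score is 0.
#'
#' @param z Z-scored matrix.
#' @param assignment `type_assignment` or a vector of labels (row order).
#' @return List with `values` (per crypt) and `mean`.
#' @export
silhouette_scores <- function(z, assignment) {
  labels <- if (inherits(assignment, "type_assignment"))
    assignment$labels$type else as.character(assignment)
  stopifnot(length(labels) == nrow(z))
  if (length(unique(labels)) < 2L) {
    stop("silhouette needs at least 2 clusters")
  }
  d <- cosine_dist_matrix(as.matrix(z))
  n <- nrow(z)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1L) { vals[i] <- 0; next }
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(d[i, labels == g]), numeric(1)))
    vals[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  list(values = vals, mean = mean(vals))
}

#' Nearest-neighbor distances between community types
#'
#' For every colonized crypt i and every target type T, computes the
#' distance from i to its nearest neighbour of type T (excluding i itself);
#' entry (S, T) of the result is the median of those distances over crypts
#' of type S. The same-type diagonal therefore uses each crypt's nearest
#' *other* member of its type. Small same-type diagonals relative to the
#' off-diagonal entries indicate that like communities colonize
#' neighbouring crypts. Type `A` — the type not enriched in any taxon — is
#' excluded by default.
#'
#' @param positions data.frame with `x`, `y` (one row per crypt).
#' @param types Character vector of type labels (same order).
#' @param exclude Types dropped from the analysis entirely
#'   (default `"A"`; use `character(0)` to keep all).
#' @return Square numeric matrix of median NN distances (um), `NA` where a
#'   type has a single member (same-type undefined).
#' @export
nn_type_distances <- function(positions, types, exclude = "A") {
  stopifnot(nrow(positions) == length(types))
  keep <- !(types %in% exclude) & !is.na(types)
  pos <- positions[keep, , drop = FALSE]
  ty <- types[keep]
  tys <- sort(unique(ty))
  n <- nrow(pos)
  d <- as.matrix(stats::dist(pos[, c("x", "y")]))
  diag(d) <- Inf
  out <- matrix(NA_real_, length(tys), length(tys),
                dimnames = list(tys, tys))
  for (s in tys) {
    rows <- which(ty == s)
    for (t in tys) {
      cols <- which(ty == t)
      nn <- vapply(rows, function(i) {
        cand <- setdiff(cols, i)
        if (!length(cand)) return(NA_real_)
        min(d[i, cand])
      }, numeric(1))
      out[s, t] <- stats::median(nn)  # NA when a same-type member is alone
    }
  }
  out
}

#' Permutation test for spatial aggregation of community types
#'
#' Tests whether crypts of the same type are spatially closer than expected
#' under exchangeable labels. The statistic is the median same-type
#' nearest-neighbour distance minus the median cross-type
#' nearest-neighbour distance over all crypts; type labels are permuted
#' uniformly and the one-sided p-value is the fraction of permutations with
#' a statistic at least as negative as observed.
#'
#' @param positions data.frame with `x`, `y`.
#' @param types Type labels.
#' @param n_perm Number of permutations.
#' @param exclude Types excluded (default `"A"`).
#' @return List with `statistic`, `p_value`, `null` (permutation
#'   statistics).
#' @export
type_spatial_permutation_test <- function(positions, types, n_perm = 199L,
                                          exclude = "A") {
  keep <- !(types %in% exclude) & !is.na(types)
  pos <- positions[keep, , drop = FALSE]
  ty <- types[keep]
  n <- nrow(pos)
  stopifnot(n >= 3L)
  d <- as.matrix(stats::dist(pos[, c("x", "y")]))
  diag(d) <- Inf
  stat <- function(lbl) {
    same <- vapply(seq_len(n), function(i) {
      cand <- which(lbl == lbl[i]); cand <- setdiff(cand, i)
      if (!length(cand)) return(NA_real_)
      min(d[i, cand])
    }, numeric(1))
    cross <- vapply(seq_len(n), function(i) {
      cand <- which(lbl != lbl[i])
      if (!length(cand)) return(NA_real_)
      min(d[i, cand])
    }, numeric(1))
    stats::median(same, na.rm = TRUE) - stats::median(cross, na.rm = TRUE)
  }
  obs <- stat(ty)
  null <- vapply(seq_len(n_perm), function(b) stat(sample(ty)), numeric(1))
  p <- (1 + sum(null <= obs)) / (n_perm + 1)
  list(statistic = obs, p_value = p, null = null)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 means identical partitions (up to label permutation), 0 is the
#' expected value under independent random partitions.
#'
#' @param a,b Label vectors of equal length.
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_ij <- sum_a * sum_b / choose(n, 2)
  max_ij <- (sum_a + sum_b) / 2
  if (max_ij == exp_ij) return(1)
  (sum_ij - exp_ij) / (max_ij - exp_ij)
}
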