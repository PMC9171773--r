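#' Per-crypt taxon volume (voxel count)
#'
#' Colony volume is measured as the voxel count of segmented objects, so
#' this accessor is the abundance primitive every downstream analysis uses.
#'
#' @param record One crypt record (one-row data.frame with
#'   `count_<taxon>` columns, as produced by [simulate_mucosa()] or read
#'   from a crypt TSV).
#' @param taxon Taxon name.
#' @return Non-negative integer voxel count.
#' @export
taxon_volume <- function(record, taxon) {
  col <- paste0("count_", taxon)
  if (!col %in% names(record)) stop("unknown taxon: ", taxon)
  as.integer(record[[col]])
}

#' Center-of-mass depth of a taxon within a crypt
#'
#' Pools the voxels of all of a taxon's objects in one crypt, projects the
#' pooled centroid onto the crypt axis (default +z) and subtracts the
#' luminal opening, so 0 is the crypt mouth and larger values are deeper.
#'
#' @param objects data.frame of segmented objects assigned to one crypt,
#'   with columns `taxon`, `voxel_count`, `z` (object centroid, um).
#' @param taxon Taxon name.
#' @param luminal_opening_z Physical z of the luminal opening plane, um.
#' @return Depth in um, or `NA` (with a warning) when the taxon has no
#'   voxels in the crypt.
#' @export
com_depth <- function(objects, taxon, luminal_opening_z = 0) {
  sel <- objects$taxon == taxon & objects$voxel_count > 0
  if (!any(sel)) {
    warning("com_depth undefined: no '", taxon, "' voxels in crypt")
    return(NA_real_)
  }
  w <- objects$voxel_count[sel]
  sum(w * objects$z[sel]) / sum(w) - luminal_opening_z
}

#' Relative depth between two taxa in one crypt
#'
#' The difference of center-of-mass depths, `depth(A) - depth(B)`, signed
#' so that positive means A sits deeper than B. A distribution of this
#' quantity centered on 0 indicates colocalization of the pair within
#' crypts; a skewed distribution indicates depth segregation.
#'
#' @param record One crypt record with `depth_<taxon>` columns.
#' @param taxon_a,taxon_b Taxon names.
#' @return Signed um, or `NA` when either taxon is absent from the crypt.
#' @export
delta_cm <- function(record, taxon_a, taxon_b) {
  ca <- paste0("depth_", taxon_a); cb <- paste0("depth_", taxon_b)
  if (!all(c(ca, cb) %in% names(record))) {
    stop("unknown taxon in delta_cm: ",
         paste(setdiff(c(taxon_a, taxon_b),
                       sub("^depth_", "", names(record))), collapse = ", "))
  }
  da <- record[[ca]]; db <- record[[cb]]
  ifelse(is.na(da) | is.na(db), NA_real_, da - db)
}

#' Density of colonized crypts per field of view
#'
#' Tiles the (x, y) plane into half-open square fields
#' `[i*e, (i+1)*e) x [j*e, (j+1)*e)` anchored at the sample bounding-box
#' minimum and counts colonized crypts per non-empty field. The default
#' edge, 425 um, is the side of one 20x confocal tile (~20 cecal crypts).
#'
#' @param crypts Crypt-record data.frame (`x`, `y`, `eub_count`).
#' @param fov_edge Field edge, um (> 0).
#' @param colonization_min Minimum eubacterial voxel count for a crypt to
#'   count as colonized (default 1).
#' @return List with `counts` (per non-empty field, in (ix, iy) order),
#'   `mean`, `sd`, and the field index table `fields`.
#' @export
colonized_density <- function(crypts, fov_edge = 425, colonization_min = 1) {
  stopifnot(fov_edge > 0)
  col <- crypts[crypts$eub_count >= colonization_min, , drop = FALSE]
  if (!nrow(col)) {
    return(list(counts = integer(0), mean = NaN, sd = NA_real_,
                fields = data.frame(ix = integer(0), iy = integer(0),
                                    count = integer(0))))
  }
  x0 <- min(crypts$x); y0 <- min(crypts$y)
  ix <- floor((col$x - x0) / fov_edge)
  iy <- floor((col$y - y0) / fov_edge)
  key <- paste(ix, iy, sep = ",")
  tab <- table(key)
  ord <- order(as.integer(sub(",.*", "", names(tab))),
               as.integer(sub(".*,", "", names(tab))))
  counts <- as.integer(tab)[ord]
  fields <- data.frame(
    ix = as.integer(sub(",.*", "", names(tab)))[ord],
    iy = as.integer(sub(".*,", "", names(tab)))[ord],
    count = counts)
  list(counts = counts, mean = mean(counts), sd = stats::sd(counts),
       fields = fields)
}

#' Distance-threshold spatial clustering of colonized crypts
#'
#' Two crypts belong to the same spatial cluster when the Euclidean
#' distance between their (x, y) centers is within the threshold (150 um by
#' default, about twice the typical distance between contiguous crypt
#' centers); clusters are the connected components of that graph. The
#' implementation buckets points on a grid of cell size `threshold` so only
#' neighbouring buckets are compared, then merges with union-find.
#'
#' @param points data.frame with `x`, `y` and optionally `crypt_id`.
#' @param threshold Neighbour distance, um (> 0).
#' @param comparator `"le"` (<=, default) or `"lt"` (<).
#' @return A list of class `spatial_clusters`: `labels` (data.frame
#'   `crypt_id`, `cluster_id`), `sizes` (per-cluster size table),
#'   `threshold`, `comparator`.
#' @export
spatial_clusters <- function(points, threshold = 150,
                             comparator = c("le", "lt")) {
  comparator <- match.arg(comparator)
  stopifnot(threshold > 0)
  n <- nrow(points)
  ids <- if ("crypt_id" %in% names(points)) points$crypt_id else seq_len(n)
  if (n == 0L) {
    return(structure(list(labels = data.frame(crypt_id = integer(0),
                                              cluster_id = integer(0)),
                          sizes = integer(0), threshold = threshold,
                          comparator = comparator),
                     class = "spatial_clusters"))
  }
  parent <- seq_len(n)
  ufind <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  cx <- floor(points$x / threshold); cy <- floor(points$y / threshold)
  cell <- split(seq_len(n), paste(cx, cy, sep = ","))
  cmp <- if (comparator == "le") `<=` else `<`
  thr2 <- threshold^2
  for (key in names(cell)) {
    here <- cell[[key]]
    kx <- as.integer(sub(",.*", "", key)); ky <- as.integer(sub(".*,", "", key))
    for (dx in -1:1) for (dy in -1:1) {
      nk <- paste(kx + dx, ky + dy, sep = ",")
      there <- cell[[nk]]
      if (is.null(there)) next
      for (i in here) for (j in there) {
        if (j <= i) next
        d2 <- (points$x[i] - points$x[j])^2 + (points$y[i] - points$y[j])^2
        if (cmp(d2, thr2)) {
          ri <- ufind(i); rj <- ufind(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), ufind, integer(1))
  lab <- match(roots, unique(roots[order(seq_len(n))]))
  structure(list(labels = data.frame(crypt_id = ids, cluster_id = lab),
                 sizes = as.integer(table(lab)), threshold = threshold,
                 comparator = comparator),
            class = "spatial_clusters")
}

#' @export
print.spatial_clusters <- function(x, ...) {
  cat("spatial_clusters:", nrow(x$labels), "crypts in",
      length(x$sizes), "clusters (threshold", x$threshold, "um,",
      x$comparator, ")\n")
  invisible(x)
}

#' Cluster-size summary (per-crypt weighted)
#'
#' Summarizes how large a cluster the typical crypt sits in: every crypt is
#' weighted by the size of its own cluster, and the 12.5th / 50th / 87.5th
#' percentiles of that per-crypt size distribution are reported (the median
#' plus the central-75% interval). Per-cluster (unweighted) quartiles are
#' reported alongside.
#'
#' @param labeling A `spatial_clusters` object.
#' @return List with `per_crypt_sizes`, `median`, `central75` (length-2),
#'   and `per_cluster` (median + quartiles over cluster sizes).
#' @export
cluster_size_summary <- function(labeling) {
  stopifnot(inherits(labeling, "spatial_clusters"),
            nrow(labeling$labels) > 0)
  sz <- labeling$sizes
  per_crypt <- sz[labeling$labels$cluster_id]
  qs <- stats::quantile(per_crypt, c(0.125, 0.5, 0.875), type = 7,
                        names = FALSE)
  list(per_crypt_sizes = as.integer(per_crypt),
       median = qs[2L], central75 = qs[c(1L, 3L)],
       per_cluster = stats::quantile(sz, c(0.25, 0.5, 0.75), type = 7,
                                     names = FALSE))
}
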