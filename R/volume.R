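#' Multi-channel 3D intensity volume
#'
#' Channel-first container for confocal imaging data: a 4D array indexed
#' `[channel, z, y, x]` with physical voxel size. Physical coordinates of a
#' voxel center are `(index - 1 + 0.5) * voxel_size` on each axis, so depth
#' along +z increases into the tissue.
#'
#' @param intensities 4D numeric array `[channel, z, y, x]`, non-negative.
#' @param voxel_size Length-3 numeric `(dz, dy, dx)`, um, all > 0.
#' @param channel_names Character vector, one per channel.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(intensities, voxel_size, channel_names) {
  stopifnot(length(dim(intensities)) == 4L,
            length(voxel_size) == 3L, all(voxel_size > 0),
            dim(intensities)[1L] == length(channel_names))
  structure(list(intensities = intensities,
                 voxel_size = as.numeric(voxel_size),
                 channel_names = as.character(channel_names)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat("voxel_volume:", d[1L], "channel(s),", d[2L], "x", d[3L], "x", d[4L],
      "voxels (z,y,x), voxel size", paste(x$voxel_size, collapse = " x "),
      "um\n  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' Emission spectra (mixing) matrix
#'
#' Detection-channel x fluorophore weight matrix describing spectral
#' overlap. Columns are normalized to unit sum on construction; an all-zero
#' column (a fluorophore invisible in every channel) is rejected.
#'
#' @param weights Channels x fluorophores non-negative matrix.
#' @param fluorophore_names Column names; defaults to existing colnames.
#' @return A normalized matrix of class `emission_spectra`.
#' @export
emission_spectra <- function(weights, fluorophore_names = colnames(weights)) {
  weights <- as.matrix(weights)
  if (any(weights < 0)) stop("emission spectra weights must be non-negative")
  cs <- colSums(weights)
  if (any(cs <= 0)) {
    stop("emission spectra: all-zero column(s): ",
         paste(which(cs <= 0), collapse = ", "))
  }
  W <- sweep(weights, 2L, cs, "/")
  colnames(W) <- fluorophore_names
  structure(W, class = c("emission_spectra", "matrix"))
}

#' Linear spectral unmixing
#'
#' Removes fluorescent spectral overlap by solving, per voxel, the
#' least-squares problem `spectra %*% a = observed` and clamping negative
#' abundances to zero. The per-voxel residual norm is retained as a QC map:
#' large residuals flag voxels whose spectrum is not explained by the
#' fluorophore panel.
#'
#' @param volume A [voxel_volume()] whose channels match the spectra rows.
#' @param spectra An [emission_spectra()] matrix (channels x fluorophores,
#'   channels >= fluorophores, full column rank).
#' @return A `voxel_volume` over the fluorophore axis, with the residual
#'   map attached as attribute `"residual"` (3D array `[z, y, x]`).
#' @export
linear_unmix <- function(volume, spectra) {
  stopifnot(inherits(volume, "voxel_volume"))
  A <- unclass(spectra)
  if (is.null(colnames(A))) colnames(A) <- paste0("f", seq_len(ncol(A)))
  d <- dim(volume$intensities)
  if (nrow(A) != d[1L]) {
    stop("spectra channel count (", nrow(A), ") != volume channel count (",
         d[1L], ")")
  }
  if (ncol(A) > nrow(A)) stop("more fluorophores than detection channels")
  qrA <- qr(A)
  if (qrA$rank < ncol(A)) {
    dep <- colnames(A)[setdiff(seq_len(ncol(A)), qrA$pivot[seq_len(qrA$rank)])]
    stop("rank-deficient spectra matrix; collinear fluorophore(s): ",
         paste(dep, collapse = ", "))
  }
  nvox <- prod(d[2:4])
  M <- matrix(volume$intensities, nrow = d[1L], ncol = nvox)
  sol <- qr.coef(qrA, M)                      # fluorophores x voxels
  fit <- A %*% sol
  resid <- sqrt(colSums((fit - M)^2))
  sol[sol < 0] <- 0
  out <- array(t(sol), dim = c(d[2:4], ncol(A)))
  out <- aperm(out, c(4L, 1L, 2L, 3L))
  res <- voxel_volume(out, volume$voxel_size, colnames(A))
  attr(res, "residual") <- array(resid, dim = d[2:4])
  res
}

# connected components over a set of voxel indices (matrix [z, y, x]),
# 26- or 6-connectivity; returns integer component labels 1..k
label_components <- function(vox, dims, connectivity = 26L) {
  parent <- NULL  # set below; union-find with path halving
  uf_find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  n <- nrow(vox)
  if (n == 0L) return(integer(0))
  nz <- dims[1L]; ny <- dims[2L]
  lin <- (vox[, 3L] - 1) * (ny * nz) + (vox[, 2L] - 1) * nz + vox[, 1L]
  ord <- order(lin)
  slin <- lin[ord]
  if (connectivity == 26L) {
    offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
    offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
    # keep one direction per pair
    keep <- offs$dx > 0 | (offs$dx == 0 & offs$dy > 0) |
      (offs$dx == 0 & offs$dy == 0 & offs$dz > 0)
    offs <- offs[keep, ]
  } else {
    offs <- data.frame(dz = c(1, 0, 0), dy = c(0, 1, 0), dx = c(0, 0, 1))
  }
  parent <- seq_len(n)
  for (k in seq_len(nrow(offs))) {
    zz <- vox[, 1L] + offs$dz[k]
    yy <- vox[, 2L] + offs$dy[k]
    xx <- vox[, 3L] + offs$dx[k]
    ok <- zz >= 1L & zz <= nz & yy >= 1L & yy <= ny & xx >= 1L & xx <= dims[3L]
    if (!any(ok)) next
    nlin <- (xx[ok] - 1) * (ny * nz) + (yy[ok] - 1) * nz + zz[ok]
    pos <- findInterval(nlin, slin)
    hit <- pos > 0L & slin[pmax(pos, 1L)] == nlin
    ia <- which(ok)[hit]
    ib <- ord[pos[hit]]
    for (m in seq_along(ia)) {
      ra <- uf_find(ia[m]); rb <- uf_find(ib[m])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), uf_find, integer(1))
  match(roots, sort(unique(roots)))
}

#' Segment a channel with an intensity filter
#'
#' Thresholds one channel and extracts connected components
#' (26-connectivity by default) of the super-threshold mask, discarding
#' components smaller than `min_voxels`. Centroids are unweighted
#' (binary-mask) centroids in physical um; set `weighted = TRUE` for
#' intensity weighting (recorded in the output attribute `"centroid_mode"`).
#'
#' @param volume A [voxel_volume()].
#' @param channel Channel name.
#' @param intensity_threshold Absolute threshold (> 0); voxels strictly
#'   above it are foreground.
#' @param min_voxels Minimum component size kept (>= 1).
#' @param connectivity 26 (default) or 6.
#' @param weighted Intensity-weighted centroids?
#' @return A data.frame of segmented objects (`object_id`, `channel`,
#'   `voxel_count`, `x`, `y`, `z`, `mean_intensity`) with the per-object
#'   voxel index lists attached as attribute `"voxels"`.
#' @export
segment_channel <- function(volume, channel, intensity_threshold,
                            min_voxels = 1L, connectivity = 26L,
                            weighted = FALSE) {
  stopifnot(inherits(volume, "voxel_volume"),
            intensity_threshold > 0, min_voxels >= 1L)
  ci <- match(channel, volume$channel_names)
  if (is.na(ci)) stop("channel not found: ", channel)
  img <- volume$intensities[ci, , , , drop = TRUE]
  if (length(dim(img)) != 3L) dim(img) <- dim(volume$intensities)[2:4]
  dims <- dim(img)
  fg <- which(img > intensity_threshold)
  empty <- data.frame(object_id = integer(0), channel = character(0),
                      voxel_count = integer(0), x = numeric(0),
                      y = numeric(0), z = numeric(0),
                      mean_intensity = numeric(0))
  if (!length(fg)) {
    attr(empty, "voxels") <- list()
    attr(empty, "centroid_mode") <- if (weighted) "weighted" else "binary"
    return(empty)
  }
  zi <- ((fg - 1L) %% dims[1L]) + 1L
  yi <- (((fg - 1L) %/% dims[1L]) %% dims[2L]) + 1L
  xi <- ((fg - 1L) %/% (dims[1L] * dims[2L])) + 1L
  vox <- cbind(z = zi, y = yi, x = xi)
  comp <- label_components(vox, dims, connectivity)
  sizes <- tabulate(comp)
  keep <- which(sizes >= min_voxels)
  if (!length(keep)) {
    attr(empty, "voxels") <- list()
    attr(empty, "centroid_mode") <- if (weighted) "weighted" else "binary"
    return(empty)
  }
  vs <- volume$voxel_size  # (dz, dy, dx)
  rows <- lapply(seq_along(keep), function(k) {
    sel <- comp == keep[k]
    v <- vox[sel, , drop = FALSE]
    ints <- img[fg[sel]]
    w <- if (weighted) ints / sum(ints) else rep(1 / nrow(v), nrow(v))
    data.frame(object_id = k, channel = channel, voxel_count = nrow(v),
               x = sum((v[, "x"] - 0.5) * vs[3L] * w),
               y = sum((v[, "y"] - 0.5) * vs[2L] * w),
               z = sum((v[, "z"] - 0.5) * vs[1L] * w),
               mean_intensity = mean(ints))
  })
  out <- do.call(rbind, rows)
  attr(out, "voxels") <- lapply(seq_along(keep), function(k)
    vox[comp == keep[k], , drop = FALSE])
  attr(out, "centroid_mode") <- if (weighted) "weighted" else "binary"
  out
}

#' Assign segmented objects to crypt regions
#'
#' Each object goes to the crypt whose axis is laterally nearest to the
#' object centroid in (x, y), provided the distance is within that crypt's
#' lateral radius; otherwise it stays unassigned. Exact distance ties break
#' toward the smaller `crypt_id`.
#'
#' @param objects data.frame from [segment_channel()] (needs `object_id`,
#'   `x`, `y`).
#' @param regions data.frame with `crypt_id`, `x`, `y`, `radius` (um).
#' @return `objects` with a `crypt_id` column (`NA` when unassigned).
#' @export
assign_objects_to_crypts <- function(objects, regions) {
  stopifnot(!anyDuplicated(regions$crypt_id), all(regions$radius > 0))
  ord <- order(regions$crypt_id)
  regions <- regions[ord, , drop = FALSE]
  assign_one <- function(ox, oy) {
    d <- sqrt((regions$x - ox)^2 + (regions$y - oy)^2)
    i <- which.min(d)  # first minimum = smallest crypt_id on ties
    if (d[i] <= regions$radius[i]) regions$crypt_id[i] else NA_integer_
  }
  objects$crypt_id <- if (nrow(objects))
    mapply(assign_one, objects$x, objects$y) else integer(0)
  objects
}

#' Signal-to-background ratio of segmented objects
#'
#' @param objects data.frame with `mean_intensity`.
#' @param background_level Scalar background intensity (> 0), typically the
#'   mean intensity of no-target / nonspecific-probe control images.
#' @return Numeric vector of per-object ratios.
#' @export
signal_to_background <- function(objects, background_level) {
  if (!is.numeric(background_level) || background_level <= 0) {
    stop("background_level must be > 0")
  }
  objects$mean_intensity / background_level
}
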