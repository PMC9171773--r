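# 3D plus-shaped blob (7 voxels) around an integer center; the elementary
# rendered bacterial aggregate
blob_offsets <- rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                      c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))

#' Render a synthetic mucosa landscape into a multi-channel volume
#'
#' Places, for every colonized crypt and taxon, small fixed-intensity blobs
#' at depths drawn from the taxon's truncated-Gaussian depth distribution
#' (so e.g. Bacilli render shallow and Bacteroidetes deep), mixes the
#' per-fluorophore images into detection channels through the configured
#' mixing matrix, and adds Gaussian intensity noise. Ground-truth per-object
#' voxel lists are recorded before mixing and noise, which makes the volume
#' a complete benchmark for unmixing and segmentation.
#'
#' Blob centers within a crypt are resampled (up to 50 tries) to keep
#' objects separated by more than one voxel, so that in sparse scenes each
#' ground-truth blob is a distinct 26-connected component; in crowded
#' crypts blobs may still touch (reported via the `crowded` flag). Voxels
#' already occupied by an earlier same-taxon object are not double-counted.
#' Blobs falling partly outside the volume bounds are clipped; a summary is
#' logged.
#'
#' The volume frame is anchored at `origin` (physical x, y of the corner,
#' chosen so all crypts fit with a margin); object coordinates are reported
#' in the volume frame, and `regions` gives the crypt centers in the same
#' frame for [assign_objects_to_crypts()].
#'
#' @param sim A `mucosa_sim` from [simulate_mucosa()].
#' @param voxels_per_blob Nominal blob size; a crypt/taxon with count `c`
#'   receives `ceiling(c / voxels_per_blob)` blobs (7 voxels each).
#' @return A list with `volume` (a [voxel_volume()], channel-first),
#'   `objects` (data.frame: `crypt_id`, `taxon`, `object_id`,
#'   `voxel_count`, `clipped`, `crowded`, centroid `x`, `y`, `z` in um,
#'   volume frame), `voxels` (list of per-object voxel index matrices
#'   `[z, y, x]`), `regions` (crypt centers in the volume frame with
#'   `radius`), and `origin` (physical (x, y) of the volume corner in the
#'   lattice frame).
#' @export
place_bacteria_and_render <- function(sim, voxels_per_blob = 7L) {
  stopifnot(inherits(sim, "mucosa_sim"))
  cfg <- sim$config
  taxa <- config_taxa(cfg)
  vs <- cfg$voxel_size  # (dz, dy, dx)
  centers <- sim$truth$centers
  margin <- cfg$crypt_radius + 4
  origin <- c(x = min(centers$x) - margin, y = min(centers$y) - margin)
  nx <- ceiling((max(centers$x) + margin - origin[["x"]]) / vs[3L])
  ny <- ceiling((max(centers$y) + margin - origin[["y"]]) / vs[2L])
  nz <- ceiling(cfg$crypt_depth / vs[1L])
  fluor <- lapply(taxa, function(t) array(0, dim = c(nz, ny, nx)))
  names(fluor) <- taxa

  obj_rows <- list(); obj_vox <- list(); oid <- 0L; n_clipped <- 0L
  with_stage_seed(cfg$rng_seed, "render", {
    for (i in which(sim$truth$colonized)) {
      placed <- matrix(numeric(0), 0, 3)  # blob centers, voxel index space
      for (t in taxa) {
        cnt <- sim$truth$counts[i, t]
        if (cnt <= 0L) next
        occupied <- matrix(integer(0), 0, 3)  # this crypt+taxon's voxels
        n_blobs <- ceiling(cnt / voxels_per_blob)
        for (b in seq_len(n_blobs)) {
          crowded <- TRUE
          for (try in 1:50) {
            ang <- stats::runif(1, 0, 2 * pi)
            rad <- sqrt(stats::runif(1)) * cfg$crypt_radius * 0.6
            px <- centers$x[i] + rad * cos(ang) - origin[["x"]]
            py <- centers$y[i] + rad * sin(ang) - origin[["y"]]
            pz <- rtruncnorm(1L, cfg$taxon_depth_means[[t]],
                             cfg$taxon_depth_sds[[t]], 0, cfg$crypt_depth)
            cz <- floor(pz / vs[1L]) + 1L
            cy <- floor(py / vs[2L]) + 1L
            cx <- floor(px / vs[3L]) + 1L
            if (nrow(placed) == 0L ||
                min((placed[, 1L] - cz)^2 + (placed[, 2L] - cy)^2 +
                    (placed[, 3L] - cx)^2) >= 25) { crowded <- FALSE; break }
          }
          placed <- rbind(placed, c(cz, cy, cx))
          vox <- sweep(blob_offsets, 2L, c(cz, cy, cx), "+")
          inb <- vox[, 1L] >= 1L & vox[, 1L] <= nz &
                 vox[, 2L] >= 1L & vox[, 2L] <= ny &
                 vox[, 3L] >= 1L & vox[, 3L] <= nx
          clipped <- !all(inb)
          if (clipped) n_clipped <- n_clipped + 1L
          vox <- vox[inb, , drop = FALSE]
          if (nrow(occupied)) {
            dup <- paste(vox[, 1L], vox[, 2L], vox[, 3L]) %in%
              paste(occupied[, 1L], occupied[, 2L], occupied[, 3L])
            vox <- vox[!dup, , drop = FALSE]
          }
          if (!nrow(vox)) next
          occupied <- rbind(occupied, vox)
          fluor[[t]][vox] <- cfg$blob_intensity
          oid <- oid + 1L
          obj_vox[[oid]] <- vox
          obj_rows[[oid]] <- data.frame(
            crypt_id = centers$crypt_id[i], taxon = t, object_id = oid,
            voxel_count = nrow(vox), clipped = clipped, crowded = crowded,
            x = mean((vox[, 3L] - 0.5) * vs[3L]),
            y = mean((vox[, 2L] - 0.5) * vs[2L]),
            z = mean((vox[, 1L] - 0.5) * vs[1L]))
        }
      }
    }
    if (n_clipped > 0L) {
      message(n_clipped, " blob(s) clipped at volume bounds")
    }
    M <- cfg$mixing_matrix
    if (is.null(M)) {
      M <- diag(length(taxa))
      dimnames(M) <- list(paste0("ch_", taxa), taxa)
    }
    stopifnot(ncol(M) == length(taxa))
    nch <- nrow(M)
    out <- array(0, dim = c(nch, nz, ny, nx))
    for (ch in seq_len(nch)) {
      acc <- array(0, dim = c(nz, ny, nx))
      for (f in seq_along(taxa)) {
        if (M[ch, f] != 0) acc <- acc + M[ch, f] * fluor[[taxa[f]]]
      }
      if (cfg$noise_sd > 0) {
        acc <- acc + stats::rnorm(length(acc), 0, cfg$noise_sd)
      }
      out[ch, , , ] <- acc
    }
    ch_names <- rownames(M)
    if (is.null(ch_names)) ch_names <- paste0("ch", seq_len(nch))
    objects <- if (oid > 0L) do.call(rbind, obj_rows) else
      data.frame(crypt_id = integer(0), taxon = character(0),
                 object_id = integer(0), voxel_count = integer(0),
                 clipped = logical(0), crowded = logical(0),
                 x = numeric(0), y = numeric(0), z = numeric(0))
    regions <- data.frame(crypt_id = centers$crypt_id,
                          x = centers$x - origin[["x"]],
                          y = centers$y - origin[["y"]],
                          radius = cfg$crypt_radius)
    list(volume = voxel_volume(out, vs, ch_names),
         objects = objects, voxels = obj_vox,
         regions = regions, origin = origin)
  })
}
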