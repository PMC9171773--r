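#' Generate a jittered crypt lattice
#'
#' Lays out crypt centers on a hexagonal (default) or square grid at the
#' configured pitch and applies isotropic Gaussian positional jitter. At the
#' default 75 um pitch a 425 x 425 um^2 field of view (one 20x tile) holds
#' on the order of 20-36 crypts, matching the density at which cecal crypts
#' are imaged.
#'
#' @param cfg A [sim_config()].
#' @return A data.frame with columns `crypt_id`, `x`, `y` (um). Deterministic
#'   under the config's `rng_seed`.
#' @export
make_crypt_lattice <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  nx <- cfg$lattice_nx; ny <- cfg$lattice_ny; p <- cfg$crypt_pitch
  ix <- rep(seq_len(nx) - 1L, times = ny)
  iy <- rep(seq_len(ny) - 1L, each = nx)
  if (cfg$lattice_geometry == "hex") {
    # odd rows shifted half a pitch; row spacing pitch * sqrt(3)/2
    x <- ix * p + (iy %% 2L) * p / 2
    y <- iy * p * sqrt(3) / 2
  } else {
    x <- ix * p
    y <- iy * p
  }
  n <- nx * ny
  if (cfg$position_jitter_sd > 0) {
    jit <- with_stage_seed(cfg$rng_seed, "lattice",
                           stats::rnorm(2L * n, 0, cfg$position_jitter_sd))
    x <- x + jit[seq_len(n)]
    y <- y + jit[n + seq_len(n)]
  }
  data.frame(crypt_id = seq_len(n), x = x, y = y)
}

#' Simulate patchy crypt colonization by seed-and-spread
#'
#' Colonization is modelled as a contact process: seed crypts are drawn
#' Bernoulli(`seed_fraction`); then for `n_spread_rounds` rounds every
#' colonized crypt attempts to colonize each still-empty neighbour (center
#' distance <= 1.5 x pitch) with probability `spread_prob`. Community-type
#' labels are drawn from the archetype prior at seeds; a spread-colonized
#' crypt copies its source's type with probability `type_spatial_coupling`,
#' otherwise draws fresh from the prior. This produces the patchy, spatially
#' clustered colonization and the spatial aggregation of like community
#' types that the downstream analyses are designed to detect.
#'
#' @param centers data.frame with `crypt_id`, `x`, `y` from
#'   [make_crypt_lattice()].
#' @param cfg A [sim_config()].
#' @return A data.frame with columns `crypt_id`, `colonized` (logical),
#'   `type` (character, `NA` for uncolonized crypts) and `seed_id` (the
#'   lattice index of the seed whose lineage colonized the crypt).
#' @export
simulate_colonization <- function(centers, cfg) {
  cfg <- validate_sim_config(cfg)
  stopifnot(nrow(centers) >= 1L)
  n <- nrow(centers)
  labels <- names(cfg$type_archetypes)
  prior <- if (is.null(cfg$type_prior))
    stats::setNames(rep(1 / length(labels), length(labels)), labels)
  else cfg$type_prior[labels]

  # neighbour lists under the 1.5 * pitch contact radius
  r <- 1.5 * cfg$crypt_pitch
  d2 <- outer(centers$x, centers$x, "-")^2 + outer(centers$y, centers$y, "-")^2
  nb <- apply(d2 <= r^2, 1L, which, simplify = FALSE)

  with_stage_seed(cfg$rng_seed, "colonization", {
    colonized <- stats::runif(n) < cfg$seed_fraction
    type <- rep(NA_character_, n)
    type[colonized] <- sample(labels, sum(colonized), replace = TRUE,
                              prob = prior)
    seed_id <- ifelse(colonized, seq_len(n), NA_integer_)
    for (round in seq_len(cfg$n_spread_rounds)) {
      src <- which(colonized)
      newly <- integer(0)
      for (i in src) {
        targets <- setdiff(nb[[i]], i)
        targets <- targets[!colonized[targets]]
        if (!length(targets)) next
        hit <- targets[stats::runif(length(targets)) < cfg$spread_prob]
        for (j in hit) {
          if (colonized[j]) next  # claimed earlier this round
          colonized[j] <- TRUE
          seed_id[j] <- seed_id[i]
          type[j] <- if (stats::runif(1) < cfg$type_spatial_coupling) type[i]
                     else sample(labels, 1L, prob = prior)
          newly <- c(newly, j)
        }
      }
      if (!length(newly)) break
    }
    data.frame(crypt_id = centers$crypt_id, colonized = colonized,
               type = type, seed_id = seed_id)
  })
}

#' Draw per-taxon voxel counts for a community type
#'
#' Counts are multiplicative-lognormal around the archetype mean:
#' `round(exp(log(mean + 1) + N(0, sd))) - 1`, clamped at zero. The +1/-1
#' shift keeps zero-mean taxa exactly at zero and the noise multiplicative
#' on the positive entries, which span orders of magnitude.
#'
#' @param type Archetype label.
#' @param cfg A [sim_config()].
#' @param n Number of independent draws (crypts).
#' @return An `n` x taxa integer matrix of voxel counts.
#' @export
sample_crypt_abundances <- function(type, cfg, n = 1L) {
  cfg <- validate_sim_config(cfg)
  if (!type %in% names(cfg$type_archetypes)) {
    stop("unknown community type: ", type)
  }
  mu <- cfg$type_archetypes[[type]]
  k <- length(mu)
  noise <- if (cfg$abundance_noise_sd > 0)
    matrix(stats::rnorm(n * k, 0, cfg$abundance_noise_sd), n, k)
  else matrix(0, n, k)
  counts <- round(exp(sweep(noise, 2L, log(mu + 1), "+"))) - 1
  counts[counts < 0] <- 0
  # an absent taxon stays absent: multiplicative noise cannot create
  # abundance where the archetype mean is zero
  counts[, mu == 0] <- 0
  storage.mode(counts) <- "integer"
  colnames(counts) <- names(mu)
  counts
}

# truncated normal by rejection; falls back to clamping for extreme
# truncation (never hit with the default depth parameters)
rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  todo <- seq_len(n)
  for (it in 1:100) {
    x <- stats::rnorm(length(todo), mean, sd)
    ok <- x >= lo & x <= hi
    out[todo[ok]] <- x[ok]
    todo <- todo[!ok]
    if (!length(todo)) return(out)
  }
  out[todo] <- pmin(pmax(stats::rnorm(length(todo), mean, sd), lo), hi)
  out
}

#' Simulate a full synthetic mucosa landscape
#'
#' Runs lattice generation, colonization, and abundance/depth sampling, and
#' assembles the crypt-record table the analysis modules consume, together
#' with complete ground truth (true types, true spatial-cluster labels via
#' the <= `cluster_threshold` connected-components rule, true depths).
#'
#' @param cfg A [sim_config()].
#' @param sample_id,condition Metadata stamped on every record.
#' @param cluster_threshold Neighbour distance (um) used for the
#'   ground-truth spatial cluster labels (default 150).
#' @return A list of class `mucosa_sim` with elements `crypts` (the
#'   crypt-record data.frame), `truth` (list: `centers`, `colonized`,
#'   `type`, `cluster`, `depths`), and `config`.
#' @export
simulate_mucosa <- function(cfg, sample_id = "S1", condition = "NA",
                            cluster_threshold = 150) {
  cfg <- validate_sim_config(cfg)
  centers <- make_crypt_lattice(cfg)
  col <- simulate_colonization(centers, cfg)
  taxa <- config_taxa(cfg)
  n <- nrow(centers)

  counts <- matrix(0L, n, length(taxa), dimnames = list(NULL, taxa))
  depths <- matrix(NA_real_, n, length(taxa), dimnames = list(NULL, taxa))
  idx <- which(col$colonized)
  with_stage_seed(cfg$rng_seed, "abundance", {
    for (i in idx) {
      counts[i, ] <- sample_crypt_abundances(col$type[i], cfg, n = 1L)
    }
  })
  with_stage_seed(cfg$rng_seed, "depth", {
    for (i in idx) {
      for (t in taxa) {
        if (counts[i, t] > 0L) {
          depths[i, t] <- rtruncnorm(1L, cfg$taxon_depth_means[[t]],
                                     cfg$taxon_depth_sds[[t]],
                                     0, cfg$crypt_depth)
        }
      }
    }
  })

  eub <- as.integer(rowSums(counts))
  eub_depth <- ifelse(eub > 0L,
                      rowSums(counts * ifelse(is.na(depths), 0, depths)) /
                        pmax(eub, 1L), NA_real_)

  crypts <- data.frame(crypt_id = centers$crypt_id, sample_id = sample_id,
                       condition = condition, x = centers$x, y = centers$y,
                       eub_count = eub, eub_depth = eub_depth)
  for (t in taxa) {
    crypts[[paste0("count_", t)]] <- counts[, t]
    crypts[[paste0("depth_", t)]] <- depths[, t]
  }

  cluster <- rep(NA_integer_, n)
  if (length(idx)) {
    lab <- spatial_clusters(centers[idx, , drop = FALSE],
                            threshold = cluster_threshold)
    cluster[idx] <- lab$labels$cluster_id
  }
  truth <- list(centers = centers, colonized = col$colonized,
                type = col$type, seed_id = col$seed_id, cluster = cluster,
                counts = counts, depths = depths,
                cluster_threshold = cluster_threshold)
  structure(list(crypts = crypts, truth = truth, config = cfg),
            class = "mucosa_sim")
}

#' @export
print.mucosa_sim <- function(x, ...) {
  cat("mucosa_sim:", nrow(x$crypts), "crypts,",
      sum(x$truth$colonized), "colonized,",
      length(unique(stats::na.omit(x$truth$type))), "community types\n")
  invisible(x)
}

#' Simulate a staining-QC gel slab experiment
#'
#' Emulates the lysozyme-permeabilization benchmark: bacterial cells are
#' embedded at uniform depths in a 0-600 um gel slab; a cell at depth d is
#' successfully stained with probability `efficiency(d)`, in which case its
#' signal-to-background ratio is drawn from a bright "stained" lognormal
#' (mean well above the S/B >= 20 detection rule), otherwise from a
#' background-level distribution with ratio near 1.
#'
#' @param n_cells Number of embedded cells.
#' @param efficiency A function depth (um) -> probability in `[0, 1]`.
#' @param depth_max Slab depth, um (default 600).
#' @param stained_meanlog,stained_sdlog Lognormal parameters of the stained
#'   S/B ratio (defaults give median ratio 200).
#' @param background_level Scalar background intensity (> 0).
#' @param seed Integer seed.
#' @return A data.frame of stain records: `cell_id`, `depth`, `hcr_signal`,
#'   `background`, `ref_detected`.
#' @export
simulate_gel_slab <- function(n_cells, efficiency, depth_max = 600,
                              stained_meanlog = log(200), stained_sdlog = 0.25,
                              background_level = 10, seed = 1L) {
  stopifnot(n_cells >= 1L, background_level > 0)
  with_stage_seed(seed, "gel", {
    depth <- stats::runif(n_cells, 0, depth_max)
    eff <- efficiency(depth)
    if (any(eff < 0 | eff > 1 | !is.finite(eff))) {
      stop("staining efficiency outside [0, 1] at a sampled depth")
    }
    stained <- stats::runif(n_cells) < eff
    ratio <- ifelse(stained,
                    stats::rlnorm(n_cells, stained_meanlog, stained_sdlog),
                    stats::rlnorm(n_cells, 0, 0.2))
    data.frame(cell_id = seq_len(n_cells), depth = depth,
               hcr_signal = ratio * background_level,
               background = background_level,
               ref_detected = TRUE)
  })
}
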