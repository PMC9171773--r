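#' Default community-type abundance archetypes
#'
#' Mean per-taxon voxel-count vectors for the six crypt community types
#' (A through F) over the three Z-scored taxonomic groups Bacteroidetes,
#' Clostridia and Bacilli. Type A is not enriched in any taxon; B is
#' Clostridia-enriched; C and F are Bacilli-enriched (C with a Clostridia
#' co-enrichment, F nearly pure); D is enriched in both Bacteroidetes and
#' Clostridia; E is Bacteroidetes-enriched. Magnitudes are in the hundreds
#' of voxels, the scale at which segmented crypt aggregates are observed.
#'
#' @return Named list of named numeric vectors (one per type).
#' @export
default_archetypes <- function() {
  taxa <- c("Bacteroidetes", "Clostridia", "Bacilli")
  mk <- function(v) stats::setNames(v, taxa)
  list(
    A = mk(c(30, 30, 30)),
    B = mk(c(60, 900, 40)),
    C = mk(c(80, 400, 700)),
    D = mk(c(800, 700, 30)),
    E = mk(c(900, 80, 40)),
    F = mk(c(40, 40, 900))
  )
}

#' Simulation configuration for the synthetic mucosa generator
#'
#' Bundles and validates every tunable of the generator: the crypt lattice,
#' the seed-and-spread colonization process, the community-type abundance
#' archetypes, the per-taxon depth stratification, and the optical rendering
#' (spectral mixing + noise). All randomness downstream flows from
#' `rng_seed` through per-stage sub-streams.
#'
#' @param lattice_nx,lattice_ny Lattice dimensions (columns, rows).
#' @param crypt_pitch Center-to-center crypt distance, um. The default 75 um
#'   is half the 150 um neighbour threshold used for spatial clustering
#'   (that threshold being about twice the typical inter-crypt distance).
#' @param lattice_geometry `"hex"` (default) or `"square"`.
#' @param position_jitter_sd Gaussian jitter SD applied to lattice
#'   positions, um.
#' @param seed_fraction Bernoulli probability that a crypt is a colonization
#'   seed.
#' @param spread_prob Per-round probability that a colonized crypt colonizes
#'   each empty neighbour (center distance <= 1.5 x pitch).
#' @param n_spread_rounds Number of spreading rounds.
#' @param type_archetypes Named list of mean abundance vectors over a common
#'   taxon set; see [default_archetypes()].
#' @param type_prior Prior over archetype labels at seed crypts; uniform by
#'   default.
#' @param type_spatial_coupling Probability that a spread-colonized crypt
#'   copies its source crypt's community type (otherwise drawn from the
#'   prior).
#' @param abundance_noise_sd Lognormal noise SD on `log(count + 1)`,
#'   dimensionless.
#' @param taxon_depth_means,taxon_depth_sds Named per-taxon depth mean/SD,
#'   um from the luminal opening (larger = deeper).
#' @param crypt_depth Depth of the crypt, um; depths are truncated to
#'   `[0, crypt_depth]`.
#' @param crypt_radius Lateral radius within which a crypt's bacteria are
#'   placed, um.
#' @param mixing_matrix Channels x fluorophores non-negative weights used
#'   when rendering a volume; identity by default (one channel per taxon).
#' @param noise_sd Additive Gaussian intensity noise SD in rendered volumes.
#' @param blob_intensity Intensity of a rendered bacterial voxel.
#' @param voxel_size Length-3 numeric `(dz, dy, dx)` in um.
#' @param rng_seed Integer master seed.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(lattice_nx = 12L, lattice_ny = 12L,
                       crypt_pitch = 75, lattice_geometry = c("hex", "square"),
                       position_jitter_sd = 5,
                       seed_fraction = 0.05, spread_prob = 0.5,
                       n_spread_rounds = 3L,
                       type_archetypes = default_archetypes(),
                       type_prior = NULL,
                       type_spatial_coupling = 0.9,
                       abundance_noise_sd = 0.3,
                       taxon_depth_means = c(Bacteroidetes = 45, Clostridia = 30, Bacilli = 15),
                       taxon_depth_sds = c(Bacteroidetes = 5, Clostridia = 5, Bacilli = 5),
                       crypt_depth = 80, crypt_radius = 20,
                       mixing_matrix = NULL, noise_sd = 0,
                       blob_intensity = 100,
                       voxel_size = c(1, 1, 1),
                       rng_seed = 1L) {
  lattice_geometry <- match.arg(lattice_geometry)
  cfg <- list(
    lattice_nx = as.integer(lattice_nx), lattice_ny = as.integer(lattice_ny),
    crypt_pitch = crypt_pitch, lattice_geometry = lattice_geometry,
    position_jitter_sd = position_jitter_sd,
    seed_fraction = seed_fraction, spread_prob = spread_prob,
    n_spread_rounds = as.integer(n_spread_rounds),
    type_archetypes = type_archetypes,
    type_prior = type_prior,
    type_spatial_coupling = type_spatial_coupling,
    abundance_noise_sd = abundance_noise_sd,
    taxon_depth_means = taxon_depth_means,
    taxon_depth_sds = taxon_depth_sds,
    crypt_depth = crypt_depth, crypt_radius = crypt_radius,
    mixing_matrix = mixing_matrix, noise_sd = noise_sd,
    blob_intensity = blob_intensity,
    voxel_size = voxel_size,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @keywords internal
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  probs <- c(seed_fraction = cfg$seed_fraction, spread_prob = cfg$spread_prob,
             type_spatial_coupling = cfg$type_spatial_coupling)
  bad <- probs < 0 | probs > 1 | !is.finite(probs)
  if (any(bad)) {
    stop("invalid sim_config: probabilities outside [0, 1]: ",
         paste(names(probs)[bad], collapse = ", "))
  }
  if (!is.finite(cfg$crypt_pitch) || cfg$crypt_pitch <= 0) {
    stop("invalid sim_config: crypt_pitch must be > 0")
  }
  if (cfg$lattice_nx < 1L || cfg$lattice_ny < 1L) {
    stop("invalid sim_config: lattice dimensions must be >= 1")
  }
  if (cfg$position_jitter_sd < 0 || cfg$abundance_noise_sd < 0 ||
      cfg$noise_sd < 0) {
    stop("invalid sim_config: noise/jitter SDs must be >= 0")
  }
  if (cfg$crypt_depth <= 0 || cfg$crypt_radius <= 0 ||
      any(cfg$voxel_size <= 0)) {
    stop("invalid sim_config: depths, radii and voxel sizes must be > 0")
  }
  taxa <- config_taxa(cfg)
  for (lab in names(cfg$type_archetypes)) {
    v <- cfg$type_archetypes[[lab]]
    if (!identical(names(v), taxa)) {
      stop("invalid sim_config: archetype '", lab,
           "' does not share the common taxon set")
    }
    if (any(v < 0)) stop("invalid sim_config: archetype '", lab,
                         "' has negative entries")
  }
  if (!all(taxa %in% names(cfg$taxon_depth_means)) ||
      !all(taxa %in% names(cfg$taxon_depth_sds))) {
    stop("invalid sim_config: taxon_depth_means/sds must cover all taxa")
  }
  if (any(cfg$taxon_depth_sds[taxa] <= 0)) {
    stop("invalid sim_config: taxon_depth_sds must be > 0")
  }
  if (!is.null(cfg$type_prior)) {
    if (!identical(sort(names(cfg$type_prior)),
                   sort(names(cfg$type_archetypes))) ||
        any(cfg$type_prior < 0) || abs(sum(cfg$type_prior) - 1) > 1e-8) {
      stop("invalid sim_config: type_prior must be a probability vector over the archetype labels")
    }
  }
  if (!is.null(cfg$mixing_matrix)) {
    M <- cfg$mixing_matrix
    if (any(M < 0)) stop("invalid sim_config: mixing_matrix must be non-negative")
    if (any(colSums(M) <= 0)) {
      stop("invalid sim_config: mixing_matrix has an all-zero column")
    }
  }
  cfg
}

#' Taxon names of a simulation configuration
#' @param cfg A `sim_config`.
#' @return Character vector of taxon names (archetype column order).
#' @export
config_taxa <- function(cfg) names(cfg$type_archetypes[[1L]])

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$lattice_nx, "x", x$lattice_ny, x$lattice_geometry,
      "lattice, pitch", x$crypt_pitch, "um\n")
  cat("  taxa:", paste(config_taxa(x), collapse = ", "), "\n")
  cat("  types:", paste(names(x$type_archetypes), collapse = ", "),
      "| coupling", x$type_spatial_coupling, "\n")
  cat("  seed_fraction", x$seed_fraction, "spread_prob", x$spread_prob,
      "rounds", x$n_spread_rounds, "\n")
  cat("  rng_seed", x$rng_seed, "\n")
  invisible(x)
}

# Per-stage RNG sub-streams: each named stage hashes to a fixed offset so
# that adding draws in one stage never perturbs another. Offsets stay
# below 2^31 - 1.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483647)
}

with_stage_seed <- function(seed, stage, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stage_seed(seed, stage))
  expr
}
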