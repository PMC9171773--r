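test_that("config validation rejects bad parameters", {
  expect_error(sim_config(crypt_pitch = 0), "crypt_pitch")
  expect_error(sim_config(seed_fraction = 1.2), "probabilities")
  expect_error(sim_config(lattice_nx = 0), "lattice")
  bad <- default_archetypes()
  bad$B <- bad$B[-1]
  expect_error(sim_config(type_archetypes = bad), "taxon set")
})

test_that("lattice geometry, jitter determinism, and field occupancy", {
  cfg <- sim_config(lattice_nx = 6, lattice_ny = 6, crypt_pitch = 75,
                    lattice_geometry = "square", position_jitter_sd = 0)
  lat <- make_crypt_lattice(cfg)
  expect_equal(nrow(lat), 36L)
  # zero-jitter square grid at pitch 75 spans 375 um: one 425 um field at
  # the origin holds all floor(425/75)+1 = 6 columns x 6 rows
  inside <- lat$x >= 0 & lat$x < 425 & lat$y >= 0 & lat$y < 425
  expect_equal(sum(inside), 36L)

  one <- make_crypt_lattice(sim_config(lattice_nx = 1, lattice_ny = 1,
                                       position_jitter_sd = 0))
  expect_equal(c(one$x, one$y), c(0, 0))

  cfg_j <- sim_config(lattice_nx = 5, lattice_ny = 4,
                      position_jitter_sd = 5, rng_seed = 99)
  expect_identical(make_crypt_lattice(cfg_j), make_crypt_lattice(cfg_j))

  hexa <- make_crypt_lattice(sim_config(lattice_nx = 3, lattice_ny = 2,
                                        position_jitter_sd = 0))
  expect_equal(hexa$x[4], 75 / 2)               # odd row offset
  expect_equal(hexa$y[4], 75 * sqrt(3) / 2)
})

test_that("colonization limits: no spreading and saturation", {
  cfg0 <- sim_config(lattice_nx = 8, lattice_ny = 8, spread_prob = 0,
                     seed_fraction = 0.3, rng_seed = 5)
  centers <- make_crypt_lattice(cfg0)
  col0 <- simulate_colonization(centers, cfg0)
  # spread_prob 0: colonized set equals the Bernoulli seed set drawn from
  # the same sub-stream
  col0b <- simulate_colonization(centers, cfg0)
  expect_identical(col0, col0b)
  cfg_spread <- cfg0; cfg_spread$spread_prob <- 0.9
  col1 <- simulate_colonization(centers, cfg_spread)
  expect_true(all(col1$colonized[col0$colonized]))

  cfg_all <- sim_config(lattice_nx = 5, lattice_ny = 5, seed_fraction = 1)
  call <- simulate_colonization(make_crypt_lattice(cfg_all), cfg_all)
  expect_true(all(call$colonized))
  expect_true(all(!is.na(call$type)))
})

test_that("spreading increases spatial cluster sizes at matched density", {
  # Monte-Carlo comparison against the brute-force clustering oracle:
  # seed-and-spread landscapes must form larger connected clusters than
  # pure Bernoulli colonization with the same expected number of crypts.
  # Clusters are measured on the contact graph (1.5 x pitch): at the
  # colonized density these settings produce (~40%), a 150 um = 2 x pitch
  # threshold connects second-shell neighbours and the Bernoulli control
  # percolates, so the wider graph cannot discriminate the mechanisms.
  n_seeds <- 50
  mean_sz <- function(cfg, seed, thr) {
    cfg$rng_seed <- seed
    centers <- make_crypt_lattice(cfg)
    col <- simulate_colonization(centers, cfg)
    idx <- which(col$colonized)
    if (length(idx) < 2) return(c(NA_real_, 0))
    lab <- oracle_clusters(centers$x[idx], centers$y[idx], thr)
    c(mean(table(lab)), length(idx))
  }
  base <- sim_config(lattice_nx = 15, lattice_ny = 15, seed_fraction = 0.02,
                     spread_prob = 0.8, n_spread_rounds = 3,
                     position_jitter_sd = 0)
  thr <- 1.5 * base$crypt_pitch
  spread <- t(vapply(seq_len(n_seeds), function(s) mean_sz(base, s, thr),
                     numeric(2)))
  matched_frac <- mean(spread[, 2]) / 225
  null_cfg <- base; null_cfg$spread_prob <- 0
  null_cfg$seed_fraction <- matched_frac
  null <- t(vapply(seq_len(n_seeds),
                   function(s) mean_sz(null_cfg, 1000 + s, thr),
                   numeric(2)))
  expect_gt(mean(spread[, 1], na.rm = TRUE), mean(null[, 1], na.rm = TRUE))
})

test_that("abundance sampling: noiseless identity, clamping, medians", {
  arch <- list(pure = c(A = 100, B = 0, C = 0),
               zero = c(A = 0, B = 0, C = 0),
               big = c(A = 1000, B = 100, C = 10))
  cfg <- sim_config(type_archetypes = arch,
                    taxon_depth_means = c(A = 10, B = 20, C = 30),
                    taxon_depth_sds = c(A = 2, B = 2, C = 2),
                    abundance_noise_sd = 0)
  expect_equal(as.vector(sample_crypt_abundances("pure", cfg)),
               c(100L, 0L, 0L))
  cfgn <- cfg; cfgn$abundance_noise_sd <- 2
  set.seed(1)
  expect_true(all(sample_crypt_abundances("zero", cfgn, n = 200) == 0L))
  expect_error(sample_crypt_abundances("nope", cfg), "unknown")

  # lognormal construction: sample median ~ archetype mean (within 5%)
  cfg3 <- cfg; cfg3$abundance_noise_sd <- 0.3
  set.seed(42)
  draws <- sample_crypt_abundances("big", cfg3, n = 10000)
  med <- apply(draws, 2, median)
  expect_true(all(abs(med - arch$big) / pmax(arch$big, 1) < 0.05))
})

test_that("simulate_mucosa ground truth is internally consistent", {
  cfg <- sim_config(lattice_nx = 10, lattice_ny = 10, rng_seed = 21)
  sim <- simulate_mucosa(cfg)
  expect_identical(sim$crypts, simulate_mucosa(cfg)$crypts)  # determinism
  col <- sim$truth$colonized
  expect_true(all(!is.na(sim$truth$type[col])))
  expect_true(all(is.na(sim$truth$type[!col])))
  # truth cluster labels match the brute-force oracle
  idx <- which(col)
  lab <- oracle_clusters(sim$truth$centers$x[idx], sim$truth$centers$y[idx],
                         150)
  expect_true(same_partition(sim$truth$cluster[idx], lab))
  # depth defined iff count > 0, and within [0, crypt_depth]
  defined <- !is.na(sim$truth$depths)
  expect_identical(defined, sim$truth$counts > 0)
  expect_true(all(sim$truth$depths[defined] >= 0 &
                    sim$truth$depths[defined] <= cfg$crypt_depth))
  # eubacterial count conserves the per-taxon counts
  expect_equal(sim$crypts$eub_count, as.integer(rowSums(sim$truth$counts)))
})

test_that("gel slab staining: limits and efficiency validation", {
  perfect <- simulate_gel_slab(500, function(d) rep(1, length(d)), seed = 3)
  expect_equal(sensitivity(perfect), 1)
  none <- simulate_gel_slab(500, function(d) rep(0, length(d)), seed = 3)
  expect_lt(sensitivity(none), 0.01)
  expect_error(simulate_gel_slab(100, function(d) d, seed = 1), "efficiency")
})
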