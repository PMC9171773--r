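test_that("taxon_volume and com_depth primitives", {
  rec <- data.frame(count_Bacteroidetes = 276L, count_Bacilli = 0L,
                    depth_Bacteroidetes = 41, depth_Bacilli = NA)
  expect_equal(taxon_volume(rec, "Bacteroidetes"), 276L)
  expect_equal(taxon_volume(rec, "Bacilli"), 0L)
  expect_error(taxon_volume(rec, "Archaea"), "unknown taxon")

  objs <- data.frame(taxon = c("A", "A", "B"), voxel_count = c(1L, 1L, 3L),
                     z = c(10, 30, 12))
  expect_equal(com_depth(objs, "A"), 20)          # mean of 10 and 30
  expect_equal(com_depth(objs, "B"), 12)
  one <- data.frame(taxon = "A", voxel_count = 1L, z = 10)
  expect_equal(com_depth(one, "A"), 10)
  expect_equal(com_depth(data.frame(taxon = "A", voxel_count = 1L, z = 0),
                         "A"), 0)                  # voxel at the opening
  expect_warning(expect_true(is.na(com_depth(objs, "C"))), "undefined")
  # weighting by voxel count
  w <- data.frame(taxon = c("A", "A"), voxel_count = c(3L, 1L), z = c(10, 30))
  expect_equal(com_depth(w, "A"), 15)
})

test_that("delta_cm: sign convention, antisymmetry, triangle identity", {
  rec <- data.frame(depth_A = 40, depth_B = 10, depth_C = 25)
  expect_equal(delta_cm(rec, "A", "B"), 30)
  expect_equal(delta_cm(rec, "A", "B"), -delta_cm(rec, "B", "A"))
  expect_equal(delta_cm(rec, "A", "C") + delta_cm(rec, "C", "B"),
               delta_cm(rec, "A", "B"))
  expect_equal(delta_cm(rec, "A", "A"), 0)
  miss <- data.frame(depth_A = 40, depth_B = NA)
  expect_true(is.na(delta_cm(miss, "A", "B")))
  expect_error(delta_cm(rec, "A", "Z"), "unknown taxon")
})

test_that("colonized density: tiling, boundary rule, exhaustive binning", {
  four <- data.frame(x = c(10, 20, 100, 400), y = c(10, 300, 200, 400),
                     eub_count = 5L)
  d <- colonized_density(four, fov_edge = 425)
  expect_equal(d$counts, 4L)
  expect_equal(d$mean, 4)
  expect_equal(d$sd, NA_real_)  # single field

  # half-open rule: x = 425 with anchor at 0 falls in the second tile
  edge <- data.frame(x = c(0, 425), y = c(0, 0), eub_count = 1L)
  d2 <- colonized_density(edge, fov_edge = 425)
  expect_equal(sort(d2$counts), c(1L, 1L))

  # 40 crypts over an 850 x 850 region -> 4 tiles, counts sum to 40
  g <- expand.grid(x = seq(0, 840, length.out = 8),
                   y = seq(0, 840, length.out = 5))
  g$eub_count <- 1L
  d3 <- colonized_density(g, fov_edge = 425)
  expect_equal(length(d3$counts), 4L)
  expect_equal(sum(d3$counts), 40L)
  expect_equal(d3$mean, 10)

  # colonization_min filters sub-threshold crypts
  mixed <- data.frame(x = 1:6, y = 0, eub_count = c(0L, 0L, 1L, 2L, 5L, 0L))
  expect_equal(colonized_density(mixed, 425)$counts, 3L)
})

test_that("spatial clustering: worked example, limits, comparator", {
  pts <- data.frame(crypt_id = 1:5, x = c(0, 100, 400, 520, 1000), y = 0)
  cl <- spatial_clusters(pts, threshold = 150)
  expect_true(same_partition(cl$labels$cluster_id, c(1, 1, 2, 2, 3)))
  expect_equal(sort(cl$sizes), c(1L, 2L, 2L))
  sm <- cluster_size_summary(cl)
  expect_equal(sort(sm$per_crypt_sizes), c(1L, 2L, 2L, 2L, 2L))
  expect_equal(sm$median, 2)

  single <- spatial_clusters(data.frame(x = 3, y = 4))
  expect_equal(single$sizes, 1L)
  all_one <- spatial_clusters(pts, threshold = 1e9)
  expect_equal(length(all_one$sizes), 1L)

  # boundary: comparator le vs lt at exactly the threshold
  two <- data.frame(x = c(0, 150), y = 0)
  expect_equal(length(spatial_clusters(two, 150, "le")$sizes), 1L)
  expect_equal(length(spatial_clusters(two, 150, "lt")$sizes), 2L)
})

test_that("spatial clustering matches the brute-force oracle", {
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(2:120, 1)
    pts <- data.frame(x = runif(n, 0, 1500), y = runif(n, 0, 1500))
    for (thr in c(50, 150, 300)) {
      got <- spatial_clusters(pts, thr)$labels$cluster_id
      want <- oracle_clusters(pts$x, pts$y, thr)
      expect_true(same_partition(got, want))
    }
  }
})

test_that("raising the threshold never increases the cluster count", {
  set.seed(8)
  pts <- data.frame(x = runif(150, 0, 2000), y = runif(150, 0, 2000))
  ns <- vapply(c(50, 100, 150, 300, 600),
               function(thr) length(spatial_clusters(pts, thr)$sizes),
               integer(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("cluster-size percentiles use per-crypt weighting", {
  # per-crypt sizes (1,1,2,2,4,4,4,4): median midpoint of 2 and 4
  lab <- structure(list(labels = data.frame(crypt_id = 1:8,
                                            cluster_id = c(1, 2, 3, 3, 4, 4, 4, 4)),
                        sizes = c(1L, 1L, 2L, 4L), threshold = 150,
                        comparator = "le"),
                   class = "spatial_clusters")
  sm <- cluster_size_summary(lab)
  expect_equal(sort(sm$per_crypt_sizes), c(1, 1, 2, 2, 4, 4, 4, 4))
  expect_equal(sm$median, 3)
  # all crypts in one cluster of 5
  lab5 <- spatial_clusters(data.frame(x = 1:5, y = 0), threshold = 10)
  expect_equal(cluster_size_summary(lab5)$median, 5)
})

test_that("recovered cluster-size median matches ground truth on synthetic data", {
  cfg <- sim_config(lattice_nx = 14, lattice_ny = 14, rng_seed = 31)
  sim <- simulate_mucosa(cfg)
  colz <- sim$crypts[sim$crypts$eub_count >= 1, ]
  got <- spatial_clusters(colz, threshold = 150)
  truth_lab <- sim$truth$cluster[sim$truth$colonized]
  expect_true(same_partition(got$labels$cluster_id, truth_lab))
  expect_equal(cluster_size_summary(got)$median,
               median(as.integer(table(truth_lab))[truth_lab]))
})
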