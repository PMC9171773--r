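test_that("Z-scoring by taxon: forced example, degenerate column, identity", {
  m <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(2, 4, 9))
  z <- zscore_by_taxon(m)
  expect_equal(z[, "a"], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(z[, "b"], c(0, 0, 0), ignore_attr = TRUE)
  expect_identical(attr(z, "zero_variance"), "b")
  expect_equal(mean(z[, "c"]), 0, tolerance = 1e-12)
  expect_equal(sd(z[, "c"]), 1, tolerance = 1e-12)
  expect_error(zscore_by_taxon(m[1, , drop = FALSE]), "at least 2 rows")
})

test_that("cosine distance: identical, orthogonal, antipodal, zero", {
  expect_equal(cosine_distance(c(1, 2), c(2, 4)), 0)
  expect_equal(cosine_distance(c(1, 0), c(0, 3)), 1)
  expect_equal(cosine_distance(c(1, 2), -c(1, 2)), 2)
  expect_warning(expect_equal(cosine_distance(c(0, 0), c(0, 0)), 0), "zero")
  expect_warning(expect_equal(cosine_distance(c(0, 0), c(1, 0)), 1), "zero")
})

test_that("hca: proportional pair merges first, heights non-decreasing", {
  z <- rbind(c(1, 1, 0), c(2, 2, 0), c(0, 0, 5))
  tree <- hca(z)
  expect_equal(sort(tree$merge[1, ]), c(-2, -1))  # the proportional pair
  expect_equal(tree$height[1], 0, tolerance = 1e-12)
  expect_true(all(diff(tree$height) >= -1e-12))
  expect_error(hca(z[1, , drop = FALSE]), "at least 2")

  set.seed(10)
  big <- matrix(rnorm(50 * 4), 50, 4)
  bt <- hca(big)
  expect_true(all(diff(bt$height) >= -1e-12))
  # taxon-axis clustering works on the transpose
  tt <- hca(big, axis = "taxa")
  expect_equal(length(tt$order), 4L)
})

test_that("cut_tree: limit cases, size-ordered labels, zero-row reassignment", {
  set.seed(2)
  z <- rbind(matrix(rnorm(10, 5), 5, 2), matrix(rnorm(6, -5), 3, 2))
  tree <- hca(z)
  a1 <- cut_tree(tree, k = 1)
  expect_equal(unique(a1$labels$type), "A")
  an <- cut_tree(tree, k = 8)
  expect_equal(length(unique(an$labels$type)), 8L)
  expect_error(cut_tree(tree, k = 9), "exceeds")
  a2 <- cut_tree(tree, k = 2)
  expect_equal(sum(a2$labels$type == "A"), 5L)  # biggest cluster is A

  # a crypt sitting exactly at every column mean has no cosine direction
  zz <- rbind(c(2, 0), c(2.5, 0.2), c(-2, 4), c(-2.5, 3.8), c(0, 0))
  tr <- hca(zz)
  asn <- cut_tree(tr, k = 2, z = zz)
  expect_true(asn$labels$reassigned[5])
  expect_true(asn$labels$type[5] %in% c("A", "B"))
})

test_that("silhouette: toy separation, degenerate zeros, random null", {
  z <- rbind(matrix(c(10, 10, 10.5, 10, 10, 10.5), 3, 2),
             matrix(c(-10, -10, -10.5, -10, -10, -10.5), 3, 2))
  lab <- rep(c("A", "B"), each = 3)
  s <- silhouette_scores(z, lab)
  expect_gt(s$mean, 0.9)
  expect_true(all(s$values >= -1 & s$values <= 1))

  ident <- matrix(1, 4, 2)
  s0 <- silhouette_scores(ident, c("A", "A", "B", "B"))
  expect_equal(s0$values, rep(0, 4))

  expect_error(silhouette_scores(z, rep("A", 6)), "at least 2")

  set.seed(55)
  means <- replicate(50, {
    zz <- matrix(rnorm(40 * 3), 40, 3)
    silhouette_scores(zz, sample(c("A", "B"), 40, TRUE))$mean
  })
  expect_lt(abs(mean(means)), 0.1)
})

test_that("silhouette agrees with the cluster-package oracle", {
  skip_if_not_installed("cluster")
  set.seed(31)
  z <- rbind(matrix(rnorm(20, 3), 10, 2), matrix(rnorm(24, -3), 12, 2))
  lab <- rep(1:2, c(10, 12))
  d <- as.dist(1 - (z / sqrt(rowSums(z^2))) %*% t(z / sqrt(rowSums(z^2))))
  want <- cluster::silhouette(lab, d)[, "sil_width"]
  got <- silhouette_scores(z, as.character(lab))$values
  expect_equal(got, as.vector(want), tolerance = 1e-10)
})

test_that("community-type recovery from well-separated archetypes (ARI = 1)", {
  cfg <- sim_config(lattice_nx = 8, lattice_ny = 8, seed_fraction = 1,
                    abundance_noise_sd = 0.1, rng_seed = 17,
                    type_archetypes = default_archetypes()[c("B", "E", "F")])
  sim <- simulate_mucosa(cfg)
  ab <- as.matrix(sim$crypts[, paste0("count_", config_taxa(cfg))])
  z <- zscore_by_taxon(ab)
  asn <- cut_tree(hca(z), k = 3)
  expect_equal(adjusted_rand_index(asn$labels$type, sim$truth$type), 1)
})

test_that("nearest-neighbor type distances: worked examples and symmetry", {
  # two crypts of one type 100 um apart
  p <- data.frame(x = c(0, 100), y = 0)
  nn <- nn_type_distances(p, c("X", "X"), exclude = character(0))
  expect_equal(nn["X", "X"], 100)

  # X at (0,0),(50,0); Y at (1000,0),(1050,0)
  p2 <- data.frame(x = c(0, 50, 1000, 1050), y = 0)
  ty2 <- c("X", "X", "Y", "Y")
  nn2 <- nn_type_distances(p2, ty2, exclude = character(0))
  expect_equal(nn2["X", "X"], 50)
  expect_equal(nn2["Y", "Y"], 50)
  # per-crypt nearest Y from the two X crypts are 1000 and 950
  expect_equal(nn2["X", "Y"], median(c(1000, 950)))

  # invariance under rigid motion
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  pr <- as.data.frame(as.matrix(p2[, c("x", "y")]) %*% t(R))
  names(pr) <- c("x", "y"); pr$x <- pr$x + 123; pr$y <- pr$y - 77
  expect_equal(nn_type_distances(pr, ty2, exclude = character(0)), nn2)

  # singleton same-type distance undefined; type A excluded by default
  p3 <- data.frame(x = c(0, 10, 500), y = 0)
  nn3 <- nn_type_distances(p3, c("B", "B", "F"), exclude = character(0))
  expect_true(is.na(nn3["F", "F"]))
  nnA <- nn_type_distances(p3, c("A", "B", "B"))
  expect_equal(rownames(nnA), "B")
})

test_that("full spatial coupling yields type-pure lineages and clusters", {
  # Under full coupling every crypt inherits its seed's type, so a spatial
  # cluster can only be type-mixed when it merges the lineages of seeds
  # that drew different types; clusters grown from a single lineage (or
  # from same-type seeds) are always pure.
  for (s in c(4, 9, 23)) {
    cfg <- sim_config(lattice_nx = 12, lattice_ny = 12,
                      type_spatial_coupling = 1, rng_seed = s)
    sim <- simulate_mucosa(cfg)
    idx <- which(sim$truth$colonized)
    ty <- sim$truth$type[idx]
    sid <- sim$truth$seed_id[idx]
    # lineage purity: type constant along each seed lineage
    expect_true(all(tapply(ty, sid, function(tt)
      length(unique(tt))) == 1L))
    # cluster impurity occurs only through merged unlike-type seeds
    cl <- sim$truth$cluster[idx]
    seed_types_per_cluster <- tapply(ty[match(unique(sid), sid)],
                                     cl[match(unique(sid), sid)],
                                     function(tt) length(unique(tt)))
    cluster_purity <- tapply(ty, cl, function(tt) length(unique(tt)))
    mixed <- names(cluster_purity)[cluster_purity > 1L]
    expect_true(all(seed_types_per_cluster[mixed] > 1L))
  }
})

test_that("adjusted Rand index: identity, permutation invariance, null", {
  a <- c(1, 1, 2, 2, 3, 3)
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, c(7, 7, 5, 5, 9, 9)), 1)
  expect_lt(adjusted_rand_index(c(1, 1, 1, 2, 2, 2), c(1, 2, 1, 2, 1, 2)), 0.5)
})
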