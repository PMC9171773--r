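# Independent oracles and tiny fixture builders shared across the suite.
# Each oracle is deliberately naive (O(n^2) scans, flood fill, full
# enumeration) and never calls the implementation path it checks.

# brute-force connected components of the <= threshold graph over 2D points
oracle_clusters <- function(x, y, threshold, comparator = `<=`) {
  n <- length(x)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- comparator(sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2),
                            threshold)
  }
  lab <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(lab[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!is.na(lab[v])) next
      lab[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(lab)))
    }
  }
  lab
}

# same partition up to label permutation
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

# brute-force flood fill over a logical 3D mask, 26-connectivity
oracle_flood_fill <- function(mask) {
  dims <- dim(mask)
  lab <- array(0L, dims)
  cur <- 0L
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    if (lab[p[1L], p[2L], p[3L]] != 0L) next
    cur <- cur + 1L
    stack <- list(p)
    while (length(stack)) {
      q <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      if (lab[q[1L], q[2L], q[3L]] != 0L) next
      lab[q[1L], q[2L], q[3L]] <- cur
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (dz == 0 && dy == 0 && dx == 0) next
        z <- q[1L] + dz; y <- q[2L] + dy; x <- q[3L] + dx
        if (z < 1 || z > dims[1L] || y < 1 || y > dims[2L] ||
            x < 1 || x > dims[3L]) next
        if (mask[z, y, x] && lab[z, y, x] == 0L) {
          stack[[length(stack) + 1L]] <- c(z, y, x)
        }
      }
    }
  }
  lab
}

# brute-force BH step-up: try every cutoff index explicitly
oracle_bh_flags <- function(p, fdr) {
  m <- length(p)
  o <- order(p)
  k <- 0L
  for (i in seq_len(m)) if (p[o[i]] <= i / m * fdr) k <- i
  reject <- logical(m)
  if (k > 0L) reject[o[seq_len(k)]] <- TRUE
  reject
}

# single-channel toy volume from a 3D array
toy_volume <- function(arr, voxel_size = c(1, 1, 1), channel = "ch1") {
  a4 <- array(arr, dim = c(1L, dim(arr)))
  voxel_volume(a4, voxel_size, channel)
}

# small sparse config whose rendered blobs stay well separated
sparse_config <- function(seed, nx = 4L, ny = 4L, ...) {
  sim_config(lattice_nx = nx, lattice_ny = ny, rng_seed = seed,
             seed_fraction = 0.6,
             type_archetypes = lapply(default_archetypes(),
                                      function(v) v / 10),
             ...)
}
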