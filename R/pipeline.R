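#' Run the full synthetic-to-analysis pipeline
#'
#' Simulates two mucosal conditions — an unexposed landscape (`"NA"`) and a
#' post-antibiotic-recovery landscape (`"AR"` with fewer seeds, smaller
#' colonies and shallower communities) — then runs every analysis stage:
#' colonized-crypt density, spatial clustering and cluster-size summaries,
#' Z-score + cosine HCA community typing with silhouettes, nearest-neighbor
#' type distances, gel-slab staining sensitivity, and the Wilcoxon + BH
#' condition comparisons. All outputs are written as deterministic TSV/JSON
#' under `out_dir`; re-running with the same seed reproduces them byte for
#' byte.
#'
#' @param seed Integer master seed.
#' @param out_dir Output directory (created if missing).
#' @param config Optional `sim_config` for the unexposed condition;
#'   defaults to [sim_config()] with `rng_seed = seed`.
#' @param k Number of community types to cut (default 6).
#' @param cluster_threshold Spatial-cluster neighbour distance, um.
#' @param fov_edge Field-of-view edge, um.
#' @return Invisibly, a list with the in-memory results.
#' @export
run_all <- function(seed = 1L, out_dir = "cryptscape_out", config = NULL,
                    k = 6L, cluster_threshold = 150, fov_edge = 425) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(seed)
  if (is.null(config)) config <- sim_config(rng_seed = seed)

  cfg_na <- config
  cfg_ar <- config
  cfg_ar$seed_fraction <- config$seed_fraction * 0.6
  cfg_ar$type_archetypes <- lapply(config$type_archetypes, function(v) v * 0.45)
  cfg_ar$taxon_depth_means <- pmax(config$taxon_depth_means - 2.5, 1)
  cfg_ar$rng_seed <- stage_seed(seed, "AR-condition")
  cfg_ar <- validate_sim_config(cfg_ar)

  sim_na <- simulate_mucosa(cfg_na, sample_id = "NA1", condition = "NA",
                            cluster_threshold = cluster_threshold)
  sim_ar <- simulate_mucosa(cfg_ar, sample_id = "AR1", condition = "AR",
                            cluster_threshold = cluster_threshold)
  crypts <- rbind(sim_na$crypts, sim_ar$crypts)
  crypts$record_id <- paste(crypts$sample_id, crypts$crypt_id, sep = ":")
  write_crypt_tsv(crypts, file.path(out_dir, "crypts.tsv"))
  write_truth_json(sim_na$truth, file.path(out_dir, "truth_NA.json"))
  write_truth_json(sim_ar$truth, file.path(out_dir, "truth_AR.json"))

  taxa <- config_taxa(config)
  results <- list(config = config, crypts = crypts)

  # --- biogeography per condition ---
  biogeo <- list()
  for (cond in c("NA", "AR")) {
    cc <- crypts[crypts$condition == cond, , drop = FALSE]
    colz <- cc[cc$eub_count >= 1, , drop = FALSE]
    dens <- colonized_density(cc, fov_edge = fov_edge)
    clus <- spatial_clusters(colz, threshold = cluster_threshold)
    summ <- if (nrow(colz)) cluster_size_summary(clus) else NULL
    biogeo[[cond]] <- list(density = dens, clusters = clus, sizes = summ)
    write_tsv_stable(merge(clus$labels,
                           colz[, c("crypt_id", "x", "y")], by = "crypt_id"),
                     file.path(out_dir, paste0("clusters_", cond, ".tsv")))
    write_tsv_stable(dens$fields,
                     file.path(out_dir, paste0("density_", cond, ".tsv")))
  }
  results$biogeo <- biogeo

  # --- community typing on pooled colonized crypts ---
  colz <- crypts[crypts$eub_count >= 1, , drop = FALSE]
  ab <- as.matrix(colz[, paste0("count_", taxa)])
  colnames(ab) <- taxa
  z <- zscore_by_taxon(ab)
  rownames(z) <- colz$record_id
  tree <- hca(z, axis = "crypts")
  assign <- cut_tree(tree, k = k, crypt_ids = colz$record_id)
  sil <- silhouette_scores(z, assign)
  typing_tab <- data.frame(record_id = assign$labels$crypt_id,
                           type = assign$labels$type,
                           silhouette = sil$values)
  write_tsv_stable(typing_tab, file.path(out_dir, "types.tsv"))
  write_tree_json(tree, file.path(out_dir, "linkage.json"))
  nn <- nn_type_distances(colz[, c("x", "y")], assign$labels$type)
  write_tsv_stable(data.frame(type = rownames(nn), as.data.frame(nn)),
                   file.path(out_dir, "nn_type_distances.tsv"))
  results$typing <- list(tree = tree, assignment = assign,
                         silhouette = sil, nn = nn)

  # --- staining QC ---
  gel <- simulate_gel_slab(5000L, function(d) exp(-d / 300),
                           seed = stage_seed(seed, "qc"))
  sens <- sensitivity(gel)
  write_tsv_stable(gel, file.path(out_dir, "stain_records.tsv"))
  results$qc <- list(records = gel, sensitivity = sens)

  # --- condition comparisons: volume and depth, overall and per taxon ---
  comps <- list()
  ok <- colz$eub_count > 0
  comps[["volume_eub"]] <- group_comparison(colz$eub_count[ok],
                                            colz$condition[ok], "volume_eub")
  okd <- !is.na(colz$eub_depth)
  comps[["depth_eub"]] <- group_comparison(colz$eub_depth[okd],
                                           colz$condition[okd], "depth_eub")
  for (t in taxa) {
    v <- colz[[paste0("count_", t)]]
    comps[[paste0("volume_", t)]] <-
      group_comparison(v, colz$condition, paste0("volume_", t))
    d <- colz[[paste0("depth_", t)]]
    keep <- !is.na(d)
    if (length(unique(colz$condition[keep])) == 2L) {
      comps[[paste0("depth_", t)]] <-
        group_comparison(d[keep], colz$condition[keep], paste0("depth_", t))
    }
  }
  comp_tab <- do.call(rbind, comps)
  bh <- bh_adjust(comp_tab$p_value, fdr = 0.1)
  comp_tab$p_adjusted <- bh$adjusted
  comp_tab$significant <- bh$reject
  rownames(comp_tab) <- NULL
  write_tsv_stable(comp_tab, file.path(out_dir, "comparisons.tsv"))
  results$comparisons <- comp_tab

  invisible(results)
}
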