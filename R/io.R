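#' Write / read the crypt-record table
#'
#' Tab-separated, UTF-8, header row, `.` decimal; numeric columns are
#' written at full precision (15 significant digits) so that re-running a
#' seeded pipeline reproduces files byte for byte.
#'
#' @param crypts Crypt-record data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_crypt_tsv <- function(crypts, path) {
  write_tsv_stable(crypts, path)
}

#' @rdname write_crypt_tsv
#' @export
read_crypt_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", check.names = FALSE,
                    na.strings = "", stringsAsFactors = FALSE)
}

# deterministic TSV writer shared by every output table
write_tsv_stable <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2)) {
    if (is.numeric(df2[[j]]) && !is.integer(df2[[j]])) {
      v <- df2[[j]]
      df2[[j]] <- ifelse(is.na(v), NA, formatC(v, digits = 15, format = "g"))
    }
  }
  # missing values are written as the empty string so that the literal
  # condition label "NA" (unexposed to antibiotic) survives round-trips
  utils::write.table(df2, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Serialize a voxel volume to JSON
#'
#' Plain-text channel-first serialization carrying dimensions, voxel size
#' (um) and channel names in metadata. Intended for small volumes
#' (fixtures, CLI round-trips); large volumes should stay in memory.
#'
#' @param volume A [voxel_volume()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_volume_json <- function(volume, path) {
  stopifnot(inherits(volume, "voxel_volume"))
  obj <- list(dims = dim(volume$intensities),
              voxel_size = volume$voxel_size,
              channel_names = volume$channel_names,
              values = as.numeric(volume$intensities))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_volume_json
#' @export
read_volume_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  arr <- array(obj$values, dim = obj$dims)
  voxel_volume(arr, obj$voxel_size, obj$channel_names)
}

#' Read a simulation configuration from YAML or JSON
#'
#' Scalar fields override the [sim_config()] defaults; `type_archetypes`
#' and `mixing_matrix` are reconstructed from nested lists.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  args <- raw
  if (!is.null(raw$type_archetypes)) {
    args$type_archetypes <- lapply(raw$type_archetypes, unlist)
  }
  if (!is.null(raw$mixing_matrix)) {
    args$mixing_matrix <- do.call(rbind, lapply(raw$mixing_matrix, unlist))
  }
  for (nm in c("taxon_depth_means", "taxon_depth_sds", "type_prior")) {
    if (!is.null(raw[[nm]])) args[[nm]] <- unlist(raw[[nm]])
  }
  do.call(sim_config, args)
}

#' Write ground truth as JSON
#' @param truth The `truth` element of a `mucosa_sim`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  obj <- list(centers = truth$centers,
              colonized = truth$colonized,
              type = truth$type,
              cluster = truth$cluster,
              cluster_threshold = truth$cluster_threshold,
              counts = as.data.frame(truth$counts),
              depths = as.data.frame(truth$depths))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA,
                       na = "null", dataframe = "columns")
  invisible(path)
}

#' Write an hclust tree as nested-list JSON
#' @param tree `hclust` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_json <- function(tree, path) {
  obj <- list(merge = tree$merge, height = tree$height,
              order = tree$order, labels = tree$labels,
              method = tree$method)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA,
                       na = "null")
  invisible(path)
}
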