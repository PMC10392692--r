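# Tabular IO: wide-format plate files with a well-metadata sheet, YAML
# run configurations, and run manifests.

#' Read a ThT plate and its metadata sheet
#'
#' The plate is tab-delimited wide format: first column time in h, one
#' column per well.  The metadata sheet maps each well to its condition
#' (\code{well}, \code{monomer_uM}, \code{seed_uM}, \code{salt_mM},
#' \code{replicate}).  Wells without metadata are an error that names the
#' orphans.
#'
#' @param path Plate TSV path.
#' @param meta_path Metadata TSV path.
#' @return List of \code{\link{tht_trace}} objects, one per well.
#' @export
read_plate <- function(path, meta_path) {
  plate <- utils::read.delim(path, check.names = FALSE)
  meta <- utils::read.delim(meta_path)
  need <- c("well", "monomer_uM", "seed_uM", "salt_mM", "replicate")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(meta$well))
    stop("duplicate well ids in metadata: ",
         paste(unique(meta$well[duplicated(meta$well)]), collapse = ", "))
  wells <- names(plate)[-1]
  if (anyDuplicated(wells))
    stop("duplicate well columns in plate: ",
         paste(unique(wells[duplicated(wells)]), collapse = ", "))
  orphans <- setdiff(wells, meta$well)
  if (length(orphans) > 0)
    stop("wells missing from metadata: ", paste(orphans, collapse = ", "))
  t <- plate[[1]]
  lapply(wells, function(w) {
    m <- meta[meta$well == w, ]
    tht_trace(t, plate[[w]], monomer_uM = m$monomer_uM,
              seed_uM = m$seed_uM, salt_mM = m$salt_mM,
              replicate = m$replicate, well = w)
  })
}

#' Write a simulated plate to disk
#'
#' @param plate A \code{\link{simulate_plate}} result.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix, default "plate".
#' @return Invisibly, the written paths (plate, metadata, truth).
#' @export
write_plate <- function(plate, dir, prefix = "plate") {
  stopifnot(inherits(plate, "tht_plate"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- file.path(dir, paste0(prefix, ".tsv"))
  m <- file.path(dir, paste0(prefix, "_meta.tsv"))
  tr <- file.path(dir, paste0(prefix, "_truth.tsv"))
  utils::write.table(plate$plate, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(plate$meta, m, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(plate$truth, tr, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(plate = p, meta = m, truth = tr))
}

#' Read and write plain-text run configurations
#'
#' Configurations are YAML key-value files.
#'
#' @param path File path.
#' @return For \code{read_config}, a named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  yaml::read_yaml(path)
}

#' @rdname read_config
#' @param config Named list to write.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records command, configuration hash, RNG seeds, package version,
#' timestamps and input/output paths of a pipeline stage as plain text,
#' so that reruns with identical inputs are reproducible.
#'
#' @param command Stage name.
#' @param inputs,outputs Character vectors of paths.
#' @param seed Integer seed(s) used by the stage.
#' @param config Optional configuration list (hashed into the manifest).
#' @param file Manifest path.
#' @return Invisibly, the path.
#' @export
write_manifest <- function(command, inputs = character(0),
                           outputs = character(0), seed = NA_integer_,
                           config = NULL, file) {
  cfg_hash <- if (is.null(config)) "none" else
    substr(tools::md5sum(files = {
      tmp <- tempfile(); yaml::write_yaml(config, tmp); tmp
    }), 1, 12)
  lines <- c(
    sprintf("command: %s", command),
    sprintf("package: saltsyn %s",
            as.character(utils::packageVersion("saltsyn"))),
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    sprintf("seed: %s", paste(seed, collapse = ",")),
    sprintf("config_hash: %s", cfg_hash),
    sprintf("input: %s", inputs),
    sprintf("output: %s", outputs))
  writeLines(lines, file)
  invisible(file)
}
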