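# Result writing and run manifests: every output directory carries a
# manifest (configuration, master seed, package version) from which the run
# can be reproduced.

#' Write stage outputs with a reproducibility manifest
#'
#' Writes each named element of `outputs` into `dir`: matrices and data
#' frames as TSV (with a unit header comment), everything else as JSON.
#' A `manifest.json` records the configuration (including the master seed)
#' and the package version.
#'
#' @param outputs named list of results
#' @param config named list describing the run (model source, stage
#'   parameters, master seed, ...)
#' @param dir output directory (created if missing)
#' @return invisibly, the paths written
#' @export
write_results <- function(outputs, config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stopifnot(!is.null(names(outputs)), all(nzchar(names(outputs))))
  paths <- character(0)
  for (nm in names(outputs)) {
    x <- outputs[[nm]]
    if (is.matrix(x) || is.data.frame(x)) {
      path <- file.path(dir, paste0(nm, ".tsv"))
      write_tsv_matrix(x, path)
    } else {
      path <- file.path(dir, paste0(nm, ".json"))
      jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE,
                           pretty = TRUE, force = TRUE)
    }
    paths <- c(paths, path)
  }
  manifest <- list(package = "colikin",
                   version = as.character(utils::packageVersion("colikin")),
                   config = config,
                   outputs = basename(paths))
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE)
  invisible(c(paths, mpath))
}

#' Write a matrix or data.frame as TSV with a unit header
#'
#' @param x matrix or data.frame
#' @param path output file
#' @param comment header comment (units and conventions)
#' @return invisibly, the path
#' @export
write_tsv_matrix <- function(x, path,
                             comment = "units: concentrations mM, time s, rates mM/s (cytoplasm basis)") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", comment), con)
  if (is.matrix(x)) {
    df <- as.data.frame(x)
    if (!is.null(rownames(x))) df <- cbind(id = rownames(x), df)
    x <- df
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a TSV written by [write_tsv_matrix()]
#'
#' @param path file path
#' @return data.frame
#' @export
read_tsv_matrix <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
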