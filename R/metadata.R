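#' Write a run-metadata file
#'
#' Records the package version, timestamp, random seed, full parameter set
#' and md5 checksums of any input files into `run_metadata.txt` in the
#' output directory, so every run is attributable and repeatable.
#'
#' @param dir Output directory.
#' @param params Named list of parameters to echo.
#' @param seed Random seed used, if any.
#' @param inputs Character vector of input file paths to checksum.
#' @return Invisibly, the metadata file path.
#' @export
write_run_metadata <- function(dir, params = list(), seed = NULL,
                               inputs = character()) {
  path <- file.path(dir, "run_metadata.txt")
  lines <- c(
    paste0("tool\thaplopair ", as.character(utils::packageVersion("haplopair"))),
    paste0("timestamp\t", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    if (!is.null(seed)) paste0("seed\t", seed),
    vapply(names(params), function(k) {
      paste0("param:", k, "\t", paste(format(params[[k]]), collapse = ","))
    }, character(1)),
    if (length(inputs) > 0L) {
      paste0("input:", basename(inputs), "\t", unname(tools::md5sum(inputs)))
    }
  )
  writeLines(lines, path)
  invisible(path)
}
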