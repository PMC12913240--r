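#' Write study artifacts to a directory
#'
#' Writes the detection-count table and trial-count accounting as TSV, the
#' cluster results and sweep correlations as JSON, and a manifest recording
#' the seeds and versions that produced them.
#'
#' @param study An `lg_study` from [run_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_results <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(study$detection, file.path(dir, "detection_table.tsv"))
  readr::write_tsv(study$trial_counts, file.path(dir, "trial_counts.tsv"))

  cl <- purrr::imap(study$clusters, function(res, nm) {
    df <- tidy(res)
    df$channels <- NULL
    df
  })
  jsonlite::write_json(cl, file.path(dir, "clusters.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  if (length(study$sweeps)) {
    sw <- purrr::imap(study$sweeps, function(s, nm)
      list(grid = as.data.frame(s$grid),
           correlations = as.data.frame(s$correlations)))
    jsonlite::write_json(sw, file.path(dir, "sweep.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  jsonlite::write_json(study$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
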