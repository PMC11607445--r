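#' Write / read a cohort as long-format delimited text
#'
#' Serializes the four cohort tables (`observations`, `treatments`, `micro`,
#' `statics`) as CSV files in a directory; `read_cohort()` restores them.
#' The round trip reproduces the cohort exactly (doubles are written with
#' round-trip precision).
#'
#' @param cohort A cohort list as produced by [simulate_cohort()] (the
#'   `cohort` element) or assembled from user data.
#' @param dir Directory to write to (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` returns
#'   the cohort list.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(is.list(cohort), nrow(cohort$observations) > 0)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("observations", "treatments", "micro", "statics")) {
    readr::write_csv(cohort[[nm]], file.path(dir, paste0(nm, ".csv")), progress = FALSE)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  spec <- list(
    observations = readr::cols(patient_id = "c", time_h = "d", variable = "c", value = "d"),
    treatments = readr::cols(patient_id = "c", start_h = "d", end_h = "d", antibiotic = "c"),
    micro = readr::cols(patient_id = "c", sample_time_h = "d", result_time_h = "d",
                        organism_class = "c", resistant_to = "c"),
    statics = readr::cols(patient_id = "c", sex = "c", age = "d", height = "d", weight = "d")
  )
  out <- lapply(names(spec), function(nm) {
    readr::read_csv(file.path(dir, paste0(nm, ".csv")), col_types = spec[[nm]], progress = FALSE)
  })
  stats::setNames(out, names(spec))
}
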