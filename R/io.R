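#' Write a PPG recording as delimited text plus a JSON sidecar
#'
#' The signal file holds one sample per line under a `# fs=<Hz>` header;
#' the sidecar carries the metadata and ground-truth annotations.
#'
#' @param record A `ppg_record`.
#' @param dir Output directory (created if needed).
#' @param stem File stem; defaults to `<patient_id>_<phase>`.
#' @return Invisibly, the signal file path.
#' @export
write_ppg_record <- function(record, dir, stem = NULL) {
  stopifnot(inherits(record, "ppg_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(stem)) stem <- paste0(record$patient_id, "_", record$phase)
  sig_path <- file.path(dir, paste0(stem, ".txt"))
  con <- file(sig_path, "w")
  writeLines(sprintf("# fs=%g", record$fs), con)
  writeLines(formatC(record$samples, format = "g", digits = 9), con)
  close(con)
  meta <- list(patient_id = record$patient_id, phase = record$phase,
               label = record$label, fs = record$fs,
               duration = record$duration,
               beat_times = record$beat_times, pac_flags = record$pac_flags)
  jsonlite::write_json(meta, file.path(dir, paste0(stem, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(sig_path)
}

#' Read a PPG recording written by [write_ppg_record()]
#'
#' @param sig_path Path to the `.txt` signal file; the `.json` sidecar is
#'   expected alongside.
#' @return A `ppg_record`.
#' @export
read_ppg_record <- function(sig_path) {
  lines <- readLines(sig_path)
  if (!grepl("^# fs=", lines[1]))
    stop_ppgaf("signal file lacks its '# fs=' header", "ppgaf_input_error")
  fs <- as.numeric(sub("^# fs=", "", lines[1]))
  samples <- as.numeric(lines[-1])
  side <- sub("\\.txt$", ".json", sig_path)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  structure(
    list(samples = samples, fs = fs, patient_id = meta$patient_id,
         phase = meta$phase, label = meta$label,
         beat_times = as.numeric(meta$beat_times),
         pac_flags = as.logical(meta$pac_flags),
         duration = meta$duration),
    class = "ppg_record"
  )
}

#' Write a cohort to a directory
#'
#' One signal/sidecar pair per recording plus a `manifest.json` listing
#' them with the per-patient generator parameters.
#'
#' @param cohort An `af_cohort`.
#' @param dir Output directory.
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "af_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  entries <- lapply(cohort$records, function(rec) {
    stem <- paste0(rec$patient_id, "_", rec$phase)
    write_ppg_record(rec, dir, stem)
    list(file = paste0(stem, ".txt"), patient_id = rec$patient_id,
         phase = rec$phase, label = rec$label)
  })
  manifest <- list(n_patients = cohort$n_patients, duration = cohort$duration,
                   fs = cohort$fs, seed = cohort$seed,
                   patients = cohort$patients, records = entries)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.json`.
#' @return An `af_cohort`.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  files <- if (is.data.frame(manifest$records)) manifest$records$file
           else vapply(manifest$records, `[[`, character(1), "file")
  records <- lapply(file.path(dir, files), read_ppg_record)
  structure(
    list(records = records, patients = as.data.frame(manifest$patients),
         n_patients = manifest$n_patients, duration = manifest$duration,
         fs = manifest$fs, seed = manifest$seed),
    class = "af_cohort"
  )
}
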