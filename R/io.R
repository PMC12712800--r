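#' Read and write waveforms and annotation tables
#'
#' Waveforms are stored as single-column delimited text with `#`-prefixed
#' header lines carrying the sampling frequency and subject id;
#' annotations as tab-separated tables with columns `beat`, `label`,
#' `sample`.
#'
#' @param recording An [scg_recording].
#' @param path File path.
#' @return `read_waveform` returns an [scg_recording];
#'   `read_annotations` an [scg_annotations].
#' @export
write_waveform <- function(recording, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# fs=", recording$fs),
               paste0("# subject=", recording$subject_id)), con)
  writeLines(format(recording$samples, digits = 12, trim = TRUE,
                    scientific = FALSE), con)
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key, default) {
    hit <- grep(paste0("^# *", key, "="), hdr, value = TRUE)
    if (length(hit)) sub(paste0("^# *", key, "="), "", hit[1]) else default
  }
  fs <- as.numeric(get("fs", NA))
  if (is.na(fs)) stop("waveform header missing fs")
  samples <- as.numeric(lines[!grepl("^#", lines)])
  scg_recording(samples, fs, subject_id = get("subject", "anon"))
}

#' @rdname write_waveform
#' @param annotations An [scg_annotations].
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_annotations <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  scg_annotations(tab$beat, tab$label, tab$sample)
}

#' Save or load a model checkpoint
#'
#' The checkpoint bundles the weights, running statistics, architecture
#' configuration, the SM name table and the training seed, so a loaded
#' model is usable and auditable without the training session.
#'
#' @param model A `unet_model`.
#' @param path File path (`.rds`).
#' @param seed Optional training seed to record.
#' @export
save_checkpoint <- function(model, path, seed = NA_integer_) {
  saveRDS(list(params = model$params, rstats = model$rstats,
               config = model$config, sm_index = sm_index(),
               seed = seed), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- unet_build(ck$config, seed = 0L)
  model$params <- ck$params
  model$rstats <- ck$rstats
  model
}
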