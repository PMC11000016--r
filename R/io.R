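# I/O glue: TSV trial tables, epoch/leadfield containers, JSON reports.

TRIAL_COLUMNS <- c("subject", "trial", "trial_type", "switching", "matching",
                   "response", "correct", "rt_s")

#' Read / write trial tables as TSV
#'
#' Tab-separated trial tables with the columns `subject, trial, trial_type,
#' switching, matching, response, correct, rt_s`. Lines starting with `#`
#' (provenance headers) are skipped on read; `writeTrials` can prepend such a
#' header. Write-then-read is the identity on these columns.
#'
#' @param trials trial table.
#' @param path file path.
#' @param header optional character vector written as `# ...` comment lines.
#' @return `readTrials` returns the data.frame; `writeTrials` returns `path`
#'   invisibly.
#' @export
writeTrials <- function(trials, path, header = NULL) {
  stopifnot_cols(trials, TRIAL_COLUMNS, "trials")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(trials[, TRIAL_COLUMNS], con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrials
#' @export
readTrials <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot_cols(df, TRIAL_COLUMNS, basename(path))
  df
}

#' Read / write EpochArray containers
#'
#' Serializes an [EpochArray-class] to a single-file container holding the
#' datasets `data`, `times_s`, `channel_names`, `condition_labels` and the
#' attributes `sfreq_hz`, `onset_sample` (RDS serialization). Round-trip
#' lossless.
#'
#' @param epochs an [EpochArray-class].
#' @param path file path.
#' @return `readEpochs` returns the [EpochArray-class]; `writeEpochs` returns
#'   `path` invisibly.
#' @export
writeEpochs <- function(epochs, path) {
  stopifnot(is(epochs, "EpochArray"))
  saveRDS(list(container = "EpochArray",
               data = epochData(epochs),
               times_s = epochTimes(epochs),
               channel_names = channelNames(epochs),
               channel_positions = channelPositions(epochs),
               condition_labels = conditionLabels(epochs),
               sfreq_hz = samplingRate(epochs),
               onset_sample = epochs@onsetSample), path)
  invisible(path)
}

#' @rdname writeEpochs
#' @export
readEpochs <- function(path) {
  x <- readRDS(path)
  if (!identical(x$container, "EpochArray"))
    stop(basename(path), " is not an EpochArray container")
  EpochArray(x$data, sfreq = x$sfreq_hz, times = x$times_s,
             channelNames = x$channel_names,
             channelPositions = x$channel_positions,
             conditions = x$condition_labels,
             onsetSample = x$onset_sample)
}

#' Read / write Leadfield containers
#' @param leadfield a [Leadfield-class].
#' @param path file path.
#' @export
writeLeadfield <- function(leadfield, path) {
  stopifnot(is(leadfield, "Leadfield"))
  saveRDS(list(container = "Leadfield",
               gain = gainMatrix(leadfield),
               voxel_positions = voxelPositions(leadfield),
               channel_positions = channelPositions(leadfield),
               channel_names = channelNames(leadfield)), path)
  invisible(path)
}

#' @rdname writeLeadfield
#' @export
readLeadfield <- function(path) {
  x <- readRDS(path)
  if (!identical(x$container, "Leadfield"))
    stop(basename(path), " is not a Leadfield container")
  new("Leadfield", gain = x$gain, voxelPositions = x$voxel_positions,
      channelPositions = x$channel_positions,
      channelNames = x$channel_names)
}

#' Read / write ground-truth coupling adjacency as JSON
#'
#' Lossless round-trip of the `groundTruth` element returned by
#' [genCoupledSources()].
#'
#' @param gt ground-truth list (`linear`, `nonlinear`, `terms`, `M`, `p`).
#' @param path file path.
#' @export
writeGroundTruth <- function(gt, path) {
  jsonlite::write_json(
    list(M = gt$M, p = gt$p,
         linear = gt$linear, nonlinear = gt$nonlinear,
         terms = lapply(gt$terms, function(tm)
           tm[c("source", "target", "lag", "fun", "gain")])),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(M = as.integer(x$M), p = as.integer(x$p),
       linear = matrix(as.logical(x$linear), x$M, x$M),
       nonlinear = matrix(as.logical(x$nonlinear), x$M, x$M),
       terms = if (length(x$terms)) lapply(seq_len(nrow(x$terms)), function(i)
         list(source = as.integer(x$terms$source[i]),
              target = as.integer(x$terms$target[i]),
              lag = as.integer(x$terms$lag[i]),
              fun = x$terms$fun[i],
              gain = x$terms$gain[i])) else list())
}

#' Write an analysis report as JSON
#'
#' @param x a named list of results.
#' @param path file path.
#' @export
writeReport <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
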