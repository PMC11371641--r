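#' Read a current trace from disk
#'
#' Two on-disk layouts are supported. HDF5: datasets `/samples` (float32) and
#' `/stimulus_times` (float64) with root attributes `sampling_rate`,
#' `start_time`, `polarity` and `annotations` (a JSON text blob). CSV: two
#' columns `time_s,current_pA` with a header, accompanied by a JSON sidecar
#' `<path>.meta.json` carrying the same metadata. HDF5 round-trips samples at
#' float32 precision of the stored values bit-exactly; CSV round-trips within
#' text precision (<= 1e-6 pA at default formatting).
#'
#' @param path File to read.
#' @param format `"hdf5"` or `"csv"`. Guessed from the file extension when
#'   omitted (`.h5`/`.hdf5` vs `.csv`).
#' @return An [epsc_trace()].
#' @seealso [write_trace()]
#' @export
read_trace <- function(path, format = c("auto", "hdf5", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "hdf5"
  if (!file.exists(path))
    stop(sprintf("trace file does not exist: %s", path), call. = FALSE)
  if (format == "hdf5") read_trace_h5(path) else read_trace_csv(path)
}

#' Write a current trace to disk
#'
#' @param trace An [epsc_trace()]; zero-length traces are rejected.
#' @param path Destination file.
#' @param format `"hdf5"` or `"csv"` (guessed from the extension by default).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, format = c("auto", "hdf5", "csv")) {
  if (!inherits(trace, "epsc_trace"))
    stop("'trace' must be an epsc_trace object", call. = FALSE)
  if (length(trace$samples) == 0L)
    stop("refusing to write a zero-length trace", call. = FALSE)
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "hdf5"
  if (!dir.exists(dirname(path)))
    stop(sprintf("directory is not writable: %s", dirname(path)), call. = FALSE)
  if (format == "hdf5") write_trace_h5(trace, path) else write_trace_csv(trace, path)
  invisible(path)
}

trace_meta_list <- function(trace) {
  list(sampling_rate = trace$sampling_rate,
       start_time = trace$start_time,
       polarity = trace$polarity,
       annotations = trace$annotations)
}

write_trace_h5 <- function(trace, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createDataset(path, "samples", dims = length(trace$samples),
                         storage.mode = "double")
  rhdf5::h5write(trace$samples, path, "samples")
  rhdf5::h5write(as.double(trace$stimulus_times), path, "stimulus_times")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  rhdf5::h5writeAttribute(trace$sampling_rate, fid, "sampling_rate")
  rhdf5::h5writeAttribute(trace$start_time, fid, "start_time")
  rhdf5::h5writeAttribute(trace$polarity, fid, "polarity")
  rhdf5::h5writeAttribute(
    as.character(jsonlite::toJSON(trace$annotations, auto_unbox = TRUE)),
    fid, "annotations")
}

read_trace_h5 <- function(path) {
  at <- rhdf5::h5readAttributes(path, "/")
  for (f in c("sampling_rate", "polarity"))
    if (is.null(at[[f]]))
      stop(sprintf("HDF5 trace is missing required attribute '%s'", f),
           call. = FALSE)
  ann <- if (is.null(at$annotations)) list() else
    jsonlite::fromJSON(as.character(at$annotations), simplifyVector = TRUE)
  epsc_trace(
    samples = as.numeric(rhdf5::h5read(path, "samples")),
    sampling_rate = as.numeric(at$sampling_rate),
    start_time = if (is.null(at$start_time)) 0 else as.numeric(at$start_time),
    polarity = as.character(at$polarity),
    stimulus_times = as.numeric(rhdf5::h5read(path, "stimulus_times")),
    annotations = as.list(ann))
}

write_trace_csv <- function(trace, path) {
  df <- data.frame(time_s = trace_times(trace), current_pA = trace$samples)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- trace_meta_list(trace)
  meta$stimulus_times <- trace$stimulus_times
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
}

read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "current_pA") %in% names(df)))
    stop(paste0("CSV trace header must contain columns 'time_s' and ",
                "'current_pA'; missing: ",
                paste(setdiff(c("time_s", "current_pA"), names(df)),
                      collapse = ", ")), call. = FALSE)
  if (nrow(df) > 1L && any(diff(df$time_s) <= 0))
    stop("CSV time column must be strictly increasing", call. = FALSE)
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path))
    stop(sprintf("CSV sidecar metadata file is missing: %s", meta_path),
         call. = FALSE)
  meta <- jsonlite::fromJSON(meta_path, simplifyVector = TRUE)
  for (f in c("sampling_rate", "polarity"))
    if (is.null(meta[[f]]))
      stop(sprintf("CSV sidecar is missing required field '%s'", f),
           call. = FALSE)
  epsc_trace(
    samples = df$current_pA,
    sampling_rate = as.numeric(meta$sampling_rate),
    start_time = if (is.null(meta$start_time)) df$time_s[1] else
      as.numeric(meta$start_time),
    polarity = as.character(meta$polarity),
    stimulus_times = as.numeric(meta$stimulus_times),
    annotations = as.list(meta$annotations))
}
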