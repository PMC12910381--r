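# Run-series inspection of total-ion chromatograms: ingest parsed
# chromatogram JSON documents and compute per-run AUC, mean and maximum
# intensity, presented as an acquisition-time-ordered series.
#
# One JSON document per run:
#   {"run_id": ..., "file_name": ..., "acquisition_time": ISO-8601,
#    "time_points": [minutes...], "tic": [intensities...], "metadata": {...}}

#' Construct a chromatogram object
#'
#' @param run_id Run identifier.
#' @param file_name Originating raw-file name.
#' @param acquisition_time POSIXct or ISO-8601 string.
#' @param time_points Retention times in minutes, strictly increasing.
#' @param tic Total-ion intensities, same length, all `>= 0`.
#' @param metadata Free-form named list.
#' @return List of class `chromatogram`.
#' @export
chromatogram <- function(run_id, file_name, acquisition_time, time_points, tic,
                         metadata = list()) {
  if (is.character(acquisition_time)) {
    acquisition_time <- as.POSIXct(acquisition_time, tz = "UTC",
                                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  }
  if (is.na(acquisition_time)) stop("chromatogram field 'acquisition_time': unparseable timestamp")
  time_points <- as.numeric(time_points)
  tic <- as.numeric(tic)
  if (length(time_points) != length(tic)) {
    stop("chromatogram fields 'time_points'/'tic': lengths differ (",
         length(time_points), " vs ", length(tic), ")")
  }
  if (length(time_points) && any(diff(time_points) <= 0)) {
    stop("chromatogram field 'time_points': not strictly increasing")
  }
  if (any(tic < 0)) stop("chromatogram field 'tic': negative intensity")
  structure(list(run_id = as.character(run_id), file_name = as.character(file_name),
                 acquisition_time = acquisition_time,
                 time_points = time_points, tic = tic, metadata = metadata),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("<chromatogram> %s: %d points over %.1f min, acquired %s\n",
              x$run_id, length(x$tic),
              if (length(x$time_points)) max(x$time_points) else 0,
              format(x$acquisition_time, "%Y-%m-%d %H:%M")))
  invisible(x)
}

#' Read a chromatogram JSON document
#' @param path Path to one run's JSON document.
#' @return A validated [chromatogram()].
#' @export
read_chromatogram_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("run_id", "file_name", "acquisition_time", "time_points", "tic")) {
    if (is.null(doc[[f]])) stop("chromatogram document missing field '", f, "'")
  }
  chromatogram(doc$run_id, doc$file_name, doc$acquisition_time,
               doc$time_points, doc$tic,
               metadata = if (is.null(doc$metadata)) list() else as.list(doc$metadata))
}

#' Write a chromatogram JSON document
#' @param chrom A [chromatogram()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chromatogram_json <- function(chrom, path) {
  jsonlite::write_json(list(
    run_id = chrom$run_id, file_name = chrom$file_name,
    acquisition_time = format(chrom$acquisition_time, "%Y-%m-%dT%H:%M:%S",
                              tz = "UTC"),
    time_points = chrom$time_points, tic = chrom$tic, metadata = chrom$metadata
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a directory of chromatogram documents
#' @param dir Directory containing `*.json` documents, one per run.
#' @return List of [chromatogram()] objects.
#' @export
read_chromatogram_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  lapply(files, read_chromatogram_json)
}

#' Per-run chromatogram metrics
#'
#' AUC by the trapezoidal rule over (time, TIC), arithmetic mean and maximum
#' intensity. AUC needs at least two points; with fewer it errors while mean
#' and max remain available via the series table.
#'
#' @param chrom A [chromatogram()].
#' @return Tibble with `run_id`, `auc` (intensity x minutes),
#'   `mean_intensity`, `max_intensity`, `n_points`.
#' @export
chromatogram_metrics <- function(chrom) {
  if (length(chrom$tic) < 2L) {
    stop("AUC undefined for fewer than 2 points (run '", chrom$run_id, "')")
  }
  tibble::tibble(
    run_id = chrom$run_id,
    auc = pracma::trapz(chrom$time_points, chrom$tic),
    mean_intensity = mean(chrom$tic),
    max_intensity = max(chrom$tic),
    n_points = length(chrom$tic)
  )
}

#' Select and order runs from a series
#'
#' Filters by run ids, file names and/or an acquisition-time window, then
#' orders by acquisition time (ties broken by run id). Requested ids that are
#' absent produce a warning and are omitted.
#'
#' @param chroms List of [chromatogram()] objects.
#' @param by_ids,by_filenames Optional character filters.
#' @param by_time_window Optional length-2 vector of POSIXct (or parseable
#'   strings) bounding the acquisition time, inclusive.
#' @return Ordered list of chromatograms.
#' @export
select_runs <- function(chroms, by_ids = NULL, by_filenames = NULL,
                        by_time_window = NULL) {
  ids <- vapply(chroms, `[[`, character(1L), "run_id")
  keep <- rep(TRUE, length(chroms))
  if (!is.null(by_ids)) {
    unknown <- setdiff(by_ids, ids)
    if (length(unknown)) warning("unknown run id(s): ", paste(unknown, collapse = ", "))
    keep <- keep & ids %in% by_ids
  }
  if (!is.null(by_filenames)) {
    fn <- vapply(chroms, `[[`, character(1L), "file_name")
    unknown <- setdiff(by_filenames, fn)
    if (length(unknown)) warning("unknown file name(s): ", paste(unknown, collapse = ", "))
    keep <- keep & fn %in% by_filenames
  }
  times <- as.POSIXct(vapply(chroms, function(x) as.numeric(x$acquisition_time), double(1L)),
                      origin = "1970-01-01", tz = "UTC")
  if (!is.null(by_time_window)) {
    w <- as.POSIXct(by_time_window, tz = "UTC")
    keep <- keep & times >= w[1L] & times <= w[2L]
  }
  sel <- which(keep)
  chroms[sel[order(times[sel], ids[sel])]]
}

#' Run-series metrics table
#'
#' One row per run in acquisition order with AUC, mean and max intensity,
#' plus per-metric relative drift (each value divided by the series median),
#' the view used to spot gradual instrument or sample-series decay.
#'
#' @param chroms Ordered list of chromatograms (see [select_runs()]).
#' @return Tibble with `run_id`, `acquisition_time`, `auc`, `mean_intensity`,
#'   `max_intensity`, `n_points` and `*_rel` drift columns.
#' @export
time_series_table <- function(chroms) {
  tab <- purrr::map_dfr(chroms, function(ch) {
    dplyr::mutate(chromatogram_metrics(ch),
                  acquisition_time = ch$acquisition_time, .after = "run_id")
  })
  if (nrow(tab) == 0L) return(tab)
  for (m in c("auc", "mean_intensity", "max_intensity")) {
    tab[[paste0(m, "_rel")]] <- tab[[m]] / stats::median(tab[[m]])
  }
  tab
}
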