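# Recording-bundle reader/writer. A bundle is a directory of plain-text
# files: ephys.csv (samples x channels, microvolts), geometry.csv,
# calcium.csv (frames x cells, dF/F), centroids.csv, meta.json (rates,
# sync offset), and optionally ground_truth.json.

#' Write a recording bundle
#'
#' Serializes a paired recording to a plain-text bundle directory.
#'
#' @param path directory to create (must not exist or be empty).
#' @param recording a `grid_recording`.
#' @param calcium a `calcium_traces` object (optional).
#' @param truth a `ground_truth` object (optional).
#' @param sync_offset_s imaging-to-ephys clock offset, seconds.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(path, recording, calcium = NULL, truth = NULL,
                         sync_offset_s = 0) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  ep <- data.table::as.data.table(t(recording$signals))
  data.table::setnames(ep, paste0("ch", recording$geometry$channel))
  data.table::fwrite(ep, file.path(path, "ephys.csv"))
  data.table::fwrite(recording$geometry, file.path(path, "geometry.csv"))
  meta <- list(ephys_rate = recording$rate, sync_offset_s = sync_offset_s)
  if (!is.null(calcium)) {
    ca <- data.table::as.data.table(t(calcium$dff))
    data.table::setnames(ca, paste0("cell", seq_len(nrow(calcium$dff))))
    data.table::fwrite(ca, file.path(path, "calcium.csv"))
    data.table::fwrite(calcium$centroids, file.path(path, "centroids.csv"))
    meta$frame_rate <- calcium$frame_rate
    meta$baseline_epoch <- range(calcium$baseline_epoch)
  }
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(truth)) {
    tr <- truth
    tr$config <- unclass(tr$config)
    tr$channel_peak_times <- NULL  # large; reconstructible from config
    jsonlite::write_json(lapply(unclass(tr), unclass),
                         file.path(path, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(path)
}

#' Read a recording bundle
#'
#' Loads and validates a bundle written by [write_bundle()]. Validation
#' failures (missing files, non-positive rates, geometry/channel
#' mismatches) are errors naming the offending field.
#'
#' @param path bundle directory.
#' @return list with `recording`, `calcium` (NULL if absent),
#'   `sync_offset_s`, `truth` (parsed JSON or NULL).
#' @export
read_bundle <- function(path) {
  need <- function(f) {
    p <- file.path(path, f)
    if (!file.exists(p)) stop(sprintf("bundle schema error: missing %s", f))
    p
  }
  meta <- jsonlite::read_json(need("meta.json"), simplifyVector = TRUE)
  if (is.null(meta$ephys_rate) || meta$ephys_rate <= 0)
    stop("bundle schema error: ephys_rate must be > 0")
  geom <- as.data.frame(data.table::fread(need("geometry.csv")))
  for (f in c("channel", "x_mm", "y_mm", "functional"))
    if (!f %in% names(geom))
      stop(sprintf("bundle schema error: geometry lacks '%s'", f))
  geom$functional <- as.logical(geom$functional)
  if (anyDuplicated(cbind(geom$x_mm, geom$y_mm)))
    stop("bundle schema error: duplicate channel positions")
  ep <- unname(as.matrix(data.table::fread(need("ephys.csv"))))
  if (ncol(ep) != nrow(geom))
    stop("bundle schema error: geometry/channel count mismatch")
  recording <- structure(list(signals = t(ep), rate = meta$ephys_rate,
                              geometry = geom),
                         class = "grid_recording")
  calcium <- NULL
  if (file.exists(file.path(path, "calcium.csv"))) {
    if (is.null(meta$frame_rate) || meta$frame_rate <= 0)
      stop("bundle schema error: frame_rate must be > 0")
    ca <- unname(as.matrix(data.table::fread(file.path(path, "calcium.csv"))))
    centroids <- as.data.frame(data.table::fread(need("centroids.csv")))
    if (nrow(centroids) != ncol(ca))
      stop("bundle schema error: centroid/cell count mismatch")
    be <- meta$baseline_epoch
    calcium <- structure(list(dff = t(ca), frame_rate = meta$frame_rate,
                              centroids = centroids,
                              baseline_epoch = seq(be[1], be[2])),
                         class = "calcium_traces")
  }
  truth <- NULL
  if (file.exists(file.path(path, "ground_truth.json")))
    truth <- jsonlite::read_json(file.path(path, "ground_truth.json"),
                                 simplifyVector = TRUE)
  list(recording = recording, calcium = calcium,
       sync_offset_s = meta$sync_offset_s %||% 0, truth = truth)
}
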