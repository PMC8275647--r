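#' Read a BIDS physiological recording
#'
#' Reads a `*_physio.tsv(.gz)` file together with its JSON sidecar
#' (`SamplingFrequency`, `StartTime`, `Columns`) and returns one
#' [raw_signal()] per requested channel. A plain two-column TSV
#' (`time`, `amplitude`) with a header is also accepted, in which case the
#' sampling rate is inferred from the time column.
#'
#' @param path Path to the `.tsv` or `.tsv.gz` file.
#' @param sidecar Path to the JSON sidecar; defaults to `path` with the
#'   extension replaced by `.json`. Ignored for two-column TSVs with a
#'   `time` column.
#' @param channels Character vector naming which sidecar columns map to
#'   which channel, e.g. `c(pulse = "cardiac", respiration = "respiratory")`.
#' @return A named list of [raw_signal()] objects.
#' @export
read_physio <- function(path, sidecar = NULL,
                        channels = c(pulse = "cardiac",
                                     respiration = "respiratory")) {
  if (!file.exists(path)) stop("physio file not found: ", path)
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", first)
  tab <- utils::read.table(path, header = has_header, sep = "\t")
  if (has_header && "time" %in% names(tab)) {
    # plain two-column format: infer timing from the time column
    dt <- diff(tab$time)
    fs <- 1 / stats::median(dt)
    amp_col <- setdiff(names(tab), "time")[1]
    ch <- if (amp_col %in% names(channels)) amp_col else "pulse"
    out <- list(raw_signal(tab[[amp_col]], fs, tab$time[1], ch))
    names(out) <- ch
    return(out)
  }
  if (is.null(sidecar)) {
    sidecar <- sub("\\.tsv(\\.gz)?$", ".json", path)
  }
  if (!file.exists(sidecar)) stop("physio sidecar not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (f in c("SamplingFrequency", "StartTime", "Columns")) {
    if (is.null(meta[[f]])) stop("malformed sidecar: missing ", f)
  }
  cols <- as.character(meta$Columns)
  if (ncol(tab) != length(cols)) {
    stop("physio TSV has ", ncol(tab), " columns but sidecar lists ",
         length(cols))
  }
  names(tab) <- cols
  out <- list()
  for (ch in names(channels)) {
    # accept the BIDS column name or the channel's own name
    col <- intersect(c(channels[[ch]], ch), cols)[1]
    if (!is.na(col)) {
      out[[ch]] <- raw_signal(tab[[col]], meta$SamplingFrequency,
                              meta$StartTime, ch)
    }
  }
  if (!length(out)) stop("none of the requested channels found in ", path)
  out
}

#' Write a BIDS-style physiological recording
#'
#' Writes the signals as a tab-separated table (gzipped when the path ends
#' in `.gz`) and a JSON sidecar with `SamplingFrequency`, `StartTime` and
#' `Columns`. All signals must share one clock.
#'
#' @param signals Named list of [raw_signal()] objects with equal sampling
#'   rate, start time and length.
#' @param path Output `.tsv` or `.tsv.gz` path.
#' @return Invisibly, the sidecar path.
#' @export
write_physio <- function(signals, path) {
  fs <- unique(vapply(signals, `[[`, numeric(1), "sampling_rate"))
  t0 <- unique(vapply(signals, `[[`, numeric(1), "start_time"))
  if (length(fs) != 1L || length(t0) != 1L) {
    stop("all signals must share sampling rate and start time")
  }
  cols <- vapply(signals, `[[`, character(1), "channel")
  tab <- as.data.frame(lapply(signals, `[[`, "samples"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  utils::write.table(tab, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  close(con)
  sidecar <- sub("\\.tsv(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(SamplingFrequency = fs, StartTime = t0, Columns = unname(cols)),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Write detected beats as a TSV table
#'
#' One row per interval: onset of the closing beat (s), interval (ms) and a
#' flag (`ok` or `corrected`).
#'
#' @param ibi An [ibi_series()].
#' @param path Output TSV path.
#' @export
write_beats <- function(ibi, path) {
  tab <- data.frame(
    onset_s = ibi$beat_times[-1L],
    ibi_ms = ibi$intervals,
    flag = ifelse(ibi$flags$corrected, "corrected", "ok"))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write HRV and breathing metrics as JSON
#'
#' @param metrics An [hrv_metrics()] result.
#' @param path Output JSON path.
#' @param br Optional breathing rate (breaths/min).
#' @param n_corrected Optional count of corrected intervals.
#' @export
write_hrv_json <- function(metrics, path, br = NULL, n_corrected = NULL) {
  out <- list(hr = metrics$hr, sdnn = metrics$sdnn, rmssd = metrics$rmssd,
              n_beats = metrics$n_beats)
  if (!is.null(br)) out$br <- br
  if (!is.null(n_corrected)) out$n_corrected <- n_corrected
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
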