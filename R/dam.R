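# TriKinetics DAM monitor files: tab-delimited text, one line per readout
# with index, date, time, a status column, auxiliary columns, and 32
# channel count columns (DAM5/DAMSystem3 "Monitor" layout).  The reader
# takes the last 32 columns as channels, which tolerates dialects that
# differ in the number of auxiliary columns.

#' Read a TriKinetics DAM monitor file
#'
#' Parses the standard 32-channel tab-delimited monitor layout into one
#' [activity_record] per channel.  Malformed lines (wrong field count or
#' non-numeric counts) are skipped with a warning giving their count;
#' inconsistent timestamp spacing is an error naming the offending line.
#'
#' @param path Monitor file path.
#' @param channels Channel indices to keep (default all 32).
#' @param drop_invalid_status Treat readings whose status column is not 1
#'   as invalid and drop those lines (default `FALSE`: keep them and
#'   record their line numbers in the `invalid_status` attribute).
#' @param light_regime,genotype Annotation applied to every channel
#'   (monitor files do not carry it).
#' @return List of [activity_record] objects, one per channel.
#' @seealso [write_dam_monitor]
#' @export
read_dam_monitor <- function(path, channels = 1:32,
                             drop_invalid_status = FALSE,
                             light_regime = "DD", genotype = "unknown") {
  if (!file.exists(path)) stop("cannot read monitor file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("monitor file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  ok <- nf >= 36 # index + date + time + status + >= 32 channels
  times <- rep(NA_real_, length(lines))
  cnt <- matrix(NA_real_, nrow = length(lines), ncol = 32)
  for (i in which(ok)) {
    f <- fields[[i]]
    tm <- as.POSIXct(paste(f[2], f[3]), tz = "UTC",
                     tryFormats = c("%d %b %y %H:%M:%S",
                                    "%d-%b-%y %H:%M:%S"))
    x <- suppressWarnings(as.numeric(f[(length(f) - 31):length(f)]))
    if (is.na(tm) || anyNA(x) || any(x < 0) || any(x != round(x))) {
      ok[i] <- FALSE
      next
    }
    times[i] <- as.numeric(tm)
    cnt[i, ] <- x
  }
  status <- vapply(fields, function(f)
    if (length(f) >= 4) suppressWarnings(as.numeric(f[4])) else NA_real_, 0)
  bad_status <- which(ok & !is.na(status) & status != 1)
  if (drop_invalid_status) ok[bad_status] <- FALSE
  n_bad <- sum(!ok)
  if (n_bad > 0)
    warning(sprintf("skipped %d malformed/invalid line(s) in %s",
                    n_bad, basename(path)))
  idx <- which(ok)
  if (length(idx) < 2) stop("fewer than 2 valid readings in ", path)
  dt <- diff(times[idx])
  bw <- stats::median(dt)
  # skipped lines leave gaps at integer multiples of the bin width;
  # anything else means the clock jumped
  off_grid <- abs(dt / bw - round(dt / bw)) * bw > 0.5 | dt < bw / 2
  if (any(off_grid)) {
    j <- idx[which(off_grid)[1] + 1]
    stop("inconsistent timestamp spacing at line ", j, " of ", path)
  }
  lapply(channels, function(ch) {
    r <- activity_record(cnt[idx, ch], bin_width_s = bw,
                         start_time = as.POSIXct(times[idx[1]],
                                                 origin = "1970-01-01",
                                                 tz = "UTC"),
                         channel_id = sprintf("ch%02d", ch),
                         light_regime = light_regime, genotype = genotype)
    if (!drop_invalid_status && length(bad_status))
      attr(r, "invalid_status") <- match(bad_status, idx)
    r
  })
}

#' Write activity records as a DAM monitor file
#'
#' Emits the standard 42-column layout (index, date, time, status, six
#' auxiliary zeros, 32 channel columns).  Up to 32 records of equal
#' length and bin width are placed in consecutive channels; remaining
#' channels are zero-filled.
#'
#' @param records List of [activity_record] objects (1--32).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dam_monitor <- function(records, path) {
  if (inherits(records, "activity_record")) records <- list(records)
  stopifnot(length(records) >= 1, length(records) <= 32,
            all(vapply(records, inherits, TRUE, "activity_record")))
  n <- unique(vapply(records, function(r) length(r$counts), 0L))
  bw <- unique(vapply(records, function(r) r$bin_width_s, 0))
  if (length(n) != 1 || length(bw) != 1)
    stop("records must share length and bin width")
  cnt <- matrix(0, nrow = n, ncol = 32)
  for (j in seq_along(records)) cnt[, j] <- records[[j]]$counts
  tms <- records[[1]]$start_time + (seq_len(n) - 1) * bw
  lines <- paste(seq_len(n),
                 format(tms, "%d %b %y"),
                 format(tms, "%H:%M:%S"),
                 1, 0, 0, 0, 0, 0, 0,
                 apply(cnt, 1, paste, collapse = "\t"),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Export a binned series with metadata
#'
#' Writes the counts of a record as two-column tab-delimited text
#' (`time_h`, `count`) next to a small JSON metadata file.
#'
#' @param record An [activity_record].
#' @param path Output path for the table; metadata goes to
#'   `paste0(path, ".json")`.
#' @export
write_record_table <- function(record, path) {
  stopifnot(inherits(record, "activity_record"))
  utils::write.table(data.frame(time_h = record_times_h(record),
                                count = record$counts),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- record[c("bin_width_s", "channel_id", "light_regime",
                   "lights_on_h", "genotype")]
  meta$start_time <- format(record$start_time, "%Y-%m-%d %H:%M:%S")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
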