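# ActivityRecord: a uniformly binned beam-crossing count series with
# light-regime annotation.  Bin i covers [i*dt, (i+1)*dt) from the record
# start (half-open convention).

#' Construct an activity record
#'
#' The universal input container of the package: a uniformly binned,
#' non-negative event-count series from one monitor channel, annotated
#' with light regime and genotype.  Averaged records (see
#' [population_average]) may carry real-valued counts.
#'
#' @param counts Numeric vector of per-bin counts (non-negative; integers
#'   for raw recordings).
#' @param bin_width_s Bin width in seconds (default 20).
#' @param start_time Timestamp of the first bin (POSIXct).
#' @param channel_id Monitor channel label.
#' @param light_regime `"LD"`, `"DD"` or `"LL"`.
#' @param lights_on_h Phase of lights-on (or subjective lights-on) in
#'   hours relative to the record start.
#' @param genotype Genotype label.
#' @return An object of class `activity_record`.
#' @export
activity_record <- function(counts, bin_width_s = 20,
                            start_time = as.POSIXct("2024-01-01 08:00:00",
                                                    tz = "UTC"),
                            channel_id = "ch01",
                            light_regime = c("DD", "LD", "LL"),
                            lights_on_h = 0, genotype = "unknown") {
  light_regime <- match.arg(light_regime)
  counts <- as.numeric(counts)
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative and free of NA")
  stopifnot(length(bin_width_s) == 1L, bin_width_s > 0)
  structure(list(counts = counts, bin_width_s = bin_width_s,
                 start_time = start_time, channel_id = channel_id,
                 light_regime = light_regime, lights_on_h = lights_on_h,
                 genotype = genotype),
            class = "activity_record")
}

#' @export
print.activity_record <- function(x, ...) {
  n <- length(x$counts)
  cat(sprintf("Activity record %s (%s, %s): %d bins of %gs (%.2f days)\n",
              x$channel_id, x$genotype, x$light_regime, n, x$bin_width_s,
              n * x$bin_width_s / 86400))
  cat(sprintf("  start %s, total %g counts, mean %.3g/bin\n",
              format(x$start_time), sum(x$counts), mean(x$counts)))
  invisible(x)
}

#' @export
length.activity_record <- function(x) length(x$counts)

# bin midpoint times in hours from record start
record_times_h <- function(record) {
  (seq_along(record$counts) - 1) * record$bin_width_s / 3600
}

#' Rebin an activity record to a wider bin
#'
#' Sums counts into consecutive groups; the new width must be an integer
#' multiple of the old, a trailing partial bin is dropped, and the total
#' count is conserved over the retained span.
#'
#' @param record An [activity_record].
#' @param new_width_s New bin width in seconds.
#' @return A rebinned [activity_record].
#' @export
rebin <- function(record, new_width_s) {
  stopifnot(inherits(record, "activity_record"))
  k <- new_width_s / record$bin_width_s
  if (abs(k - round(k)) > 1e-9 || k < 1)
    stop("new_width_s must be an integer multiple of the current bin width")
  k <- as.integer(round(k))
  if (k == 1L) return(record)
  n <- length(record$counts) %/% k
  x <- record$counts[seq_len(n * k)]
  out <- record
  out$counts <- colSums(matrix(x, nrow = k))
  out$bin_width_s <- record$bin_width_s * k
  out
}

#' Drop the first day after release into constant darkness
#'
#' Transient behaviour on the first day of constant darkness after
#' entrainment is excluded from analysis; this removes the first 24 h of
#' a DD record.  Idempotent: trimming an already-trimmed record (or an LD
#' record) warns and returns it unchanged.
#'
#' @param record An [activity_record].
#' @return The trimmed record, flagged so a second trim is a no-op.
#' @export
trim_entrainment <- function(record) {
  stopifnot(inherits(record, "activity_record"))
  if (record$light_regime != "DD") {
    warning("record is not a DD recording; returning unchanged")
    return(record)
  }
  if (isTRUE(attr(record, "entrainment_trimmed"))) {
    warning("record already trimmed; returning unchanged")
    return(record)
  }
  nday <- round(86400 / record$bin_width_s)
  if (length(record$counts) <= nday)
    stop("record shorter than one day; nothing would remain after trimming")
  out <- record
  out$counts <- record$counts[-seq_len(nday)]
  out$start_time <- record$start_time + 86400
  attr(out, "entrainment_trimmed") <- TRUE
  if (length(out$counts) * out$bin_width_s < 2 * 86400)
    warning("fewer than 2 days remain after trimming")
  out
}

#' Average aligned activity records across individuals
#'
#' Per-bin arithmetic mean of records with identical bin width and start
#' time; the result carries real-valued counts.
#'
#' @param records List of [activity_record] objects.
#' @return An averaged [activity_record].
#' @export
population_average <- function(records) {
  stopifnot(length(records) >= 1,
            all(vapply(records, inherits, TRUE, "activity_record")))
  bw <- vapply(records, function(r) r$bin_width_s, 0)
  st <- vapply(records, function(r) as.numeric(r$start_time), 0)
  ns <- vapply(records, function(r) length(r$counts), 0L)
  if (length(unique(bw)) != 1L || length(unique(ns)) != 1L ||
      diff(range(st)) > bw[1] / 2)
    stop("records must share bin width, length and start time")
  out <- records[[1]]
  out$counts <- rowMeans(vapply(records, function(r) r$counts,
                                numeric(ns[1])))
  out$channel_id <- sprintf("avg_of_%d", length(records))
  out
}
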