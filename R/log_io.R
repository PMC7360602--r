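# Plain-text log formats: per-mouse event logs, per-mouse daily weight
# files, and the per-run summary table.  The device's own convention names
# no timestamp format or delimiter, so this package fixes a dialect --
# ISO-8601 timestamps at millisecond resolution, tab-delimited event and
# weight rows, a comma-separated summary with a header -- and guarantees
# lossless round trips: write -> parse -> write is byte-identical.

.ISO_RE <- "^(\\d{4}-\\d{2}-\\d{2})T(\\d{2}:\\d{2}:\\d{2})\\.(\\d{3})$"

#' Format times as ISO-8601 with milliseconds
#' @param time POSIXct vector (UTC).
#' @return Character vector like `"2024-01-02T03:04:05.678"`.
#' @export
format_iso_ms <- function(time) {
  ms <- round(as.numeric(time) * 1000)
  base <- format(.POSIXct(ms %/% 1000, tz = "UTC"), "%Y-%m-%dT%H:%M:%S")
  sprintf("%s.%03d", base, ms %% 1000)
}

#' Parse ISO-8601 millisecond timestamps
#' @param x character vector as produced by [format_iso_ms()].
#' @return POSIXct vector (UTC); unparseable elements raise an error.
#' @export
parse_iso_ms <- function(x) {
  m <- regmatches(x, regexec(.ISO_RE, x))
  bad <- which(vapply(m, length, 0L) == 0L)
  if (length(bad))
    stop(sprintf("malformed timestamp '%s'", x[bad[1]]), call. = FALSE)
  base <- as.POSIXct(strptime(sub("\\.\\d{3}$", "", x),
                              "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  if (anyNA(base))
    stop(sprintf("malformed timestamp '%s'", x[which(is.na(base))[1]]),
         call. = FALSE)
  base + as.numeric(sub("^.*\\.", "", x)) / 1000
}

.event_log_path <- function(dir, tag) file.path(dir, paste0(tag, "_events.txt"))

.validate_events <- function(events) {
  stopifnot(is.data.frame(events),
            all(c("time", "tag", "code") %in% names(events)))
  bad <- setdiff(unique(events$code), EVENT_CODES)
  if (length(bad))
    stop(sprintf("unknown event code '%s'", bad[1]), call. = FALSE)
  invisible(events)
}

.event_lines <- function(events) {
  iso <- format_iso_ms(events$time)
  payload <- if ("payload" %in% names(events)) events$payload else
    character(nrow(events))
  payload[is.na(payload)] <- ""
  ifelse(nzchar(payload), paste(iso, events$code, payload, sep = "\t"),
         paste(iso, events$code, sep = "\t"))
}

#' Write per-mouse event log files
#'
#' Splits an event table by tag and writes one `<tag>_events.txt` per mouse
#' (cage-level events go to `CAGE_events.txt`).  Rows are
#' `timestamp<TAB>code[<TAB>payload]`.  Out-of-order timestamps within one
#' stream are rejected.
#'
#' @param events `data.frame` with columns `time` (POSIXct), `tag`, `code`
#'   and optionally `payload`.
#' @param dir output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_event_logs <- function(events, dir) {
  .validate_events(events)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (tag in unique(events$tag)) {
    sub <- events[events$tag == tag, , drop = FALSE]
    if (is.unsorted(as.numeric(sub$time)))
      stop(sprintf("out-of-order timestamps in event stream for '%s'", tag),
           call. = FALSE)
    path <- .event_log_path(dir, tag)
    writeLines(.event_lines(sub), path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Parse one per-mouse event log file
#'
#' Lossless inverse of [write_event_logs()] for a single file; the tag is
#' recovered from the file name.
#'
#' @param path path to a `<tag>_events.txt` file.
#' @return `data.frame` with columns `time`, `tag`, `code`, `payload`.
#' @export
parse_event_log <- function(path) {
  tag <- sub("_events\\.txt$", "", basename(path))
  lines <- readLines(path)
  if (length(lines) == 0L)
    return(data.frame(time = as.POSIXct(character(), tz = "UTC"),
                      tag = character(), code = character(),
                      payload = character(), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 2L | nf > 3L)
  if (length(bad))
    stop(sprintf("parse error at line %d of '%s'", bad[1], path), call. = FALSE)
  time <- tryCatch(parse_iso_ms(vapply(parts, `[[`, "", 1L)),
                   error = function(e)
                     stop(sprintf("parse error in '%s': %s", path,
                                  conditionMessage(e)), call. = FALSE))
  code <- vapply(parts, `[[`, "", 2L)
  unknown <- which(!code %in% EVENT_CODES)
  if (length(unknown))
    stop(sprintf("unknown event code '%s' at line %d of '%s'",
                 code[unknown[1]], unknown[1], path), call. = FALSE)
  payload <- vapply(parts, function(p) if (length(p) == 3L) p[[3L]] else "", "")
  data.frame(time = time, tag = tag, code = code, payload = payload,
             stringsAsFactors = FALSE)
}

#' Parse every event log in a directory into one stream
#'
#' @param dir directory containing `*_events.txt` files.
#' @return Combined `data.frame` sorted by time (ties keep file order).
#' @export
parse_event_logs <- function(dir) {
  files <- sort(list.files(dir, pattern = "_events\\.txt$", full.names = TRUE))
  out <- do.call(rbind, lapply(files, parse_event_log))
  out[order(as.numeric(out$time)), , drop = FALSE]
}

#' Write per-mouse daily weight files
#'
#' One `<tag>_weights_<YYYY-MM-DD>.txt` per calendar day present in the
#' samples, rows `timestamp<TAB>grams` with grams to 2 decimal places; a
#' new file starts at midnight.
#'
#' @param samples `data.frame` with columns `time` (POSIXct) and `grams`.
#' @param tag the mouse tag.
#' @param dir output directory.
#' @return Character vector of the files written, invisibly.
#' @export
write_weight_files <- function(samples, tag, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.unsorted(as.numeric(samples$time)))
    stop("out-of-order timestamps in weight samples", call. = FALSE)
  dates <- as.Date(samples$time, tz = "UTC")
  paths <- character(0)
  for (d in unique(as.character(dates))) {
    sub <- samples[dates == d, , drop = FALSE]
    path <- file.path(dir, sprintf("%s_weights_%s.txt", tag, d))
    writeLines(sprintf("%s\t%.2f", format_iso_ms(sub$time), sub$grams), path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Parse one daily weight file
#'
#' @param path path to a `<tag>_weights_<date>.txt` file.
#' @return `data.frame` with columns `time`, `tag`, `grams`.
#' @export
parse_weight_file <- function(path) {
  base <- basename(path)
  tag <- sub("_weights_\\d{4}-\\d{2}-\\d{2}\\.txt$", "", base)
  lines <- readLines(path)
  if (length(lines) == 0L)
    return(data.frame(time = as.POSIXct(character(), tz = "UTC"),
                      tag = character(), grams = numeric(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop(sprintf("parse error at line %d of '%s'", bad[1], path), call. = FALSE)
  grams <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(grams))
    stop(sprintf("parse error at line %d of '%s'", which(is.na(grams))[1], path),
         call. = FALSE)
  data.frame(time = parse_iso_ms(vapply(parts, `[[`, "", 1L)),
             tag = tag, grams = grams, stringsAsFactors = FALSE)
}

.SUMMARY_HEADER <- "date,tag,weight_g,water_drops,drug_drops,drug_ug"

#' Write the treatment summary table
#'
#' Comma-separated with a header; exactly one row per mouse per day of the
#' run.  Weights print to 1 decimal place (the estimator's resolution) and
#' drug mass to 2.
#'
#' @param summary `data.frame` with columns `date`, `tag`, `weight_g`,
#'   `water_drops`, `drug_drops`, `drug_ug`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  need <- c("date", "tag", "weight_g", "water_drops", "drug_drops", "drug_ug")
  stopifnot(all(need %in% names(summary)))
  w <- ifelse(is.na(summary$weight_g), "NA", sprintf("%.1f", summary$weight_g))
  lines <- c(.SUMMARY_HEADER,
             sprintf("%s,%s,%s,%d,%d,%.2f", as.character(summary$date),
                     summary$tag, w, as.integer(summary$water_drops),
                     as.integer(summary$drug_drops), summary$drug_ug))
  writeLines(lines, path)
  invisible(path)
}

#' Parse a treatment summary table
#'
#' @param path path written by [write_summary()].
#' @return `data.frame` with typed columns (`date` as `Date`).
#' @export
parse_summary <- function(path) {
  first <- readLines(path, n = 1L)
  if (!identical(first, .SUMMARY_HEADER))
    stop(sprintf("parse error: unexpected header in '%s'", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(date = "character", tag = "character"))
  df$date <- as.Date(df$date)
  df
}

#' Build the summary table from events and daily weight estimates
#'
#' Tallies `DROP_WATER` / `DROP_DRUG` per mouse-day from the event stream
#' and joins the daily weight estimates; drug mass is the drop count times
#' the drop quantum.  Days whose weight was carried forward keep the
#' carried value (the `carried` flag travels in the estimates table).
#'
#' @param events event `data.frame` (see [controller_events()]).
#' @param estimates estimates `data.frame` from [controller_finalize()]
#'   (columns `tag`, `date`, `grams`, `carried`).
#' @param config a [system_config()].
#' @return Summary `data.frame`, one row per mouse-day, sorted by date then
#'   tag.
#' @export
build_summary <- function(events, estimates, config) {
  drops <- events[events$code %in% c("DROP_WATER", "DROP_DRUG"), , drop = FALSE]
  key <- function(tag, date) paste(tag, as.character(date), sep = "\r")
  dkey <- key(drops$tag, as.Date(drops$time, tz = "UTC"))
  water <- table(dkey[drops$code == "DROP_WATER"])
  drug <- table(dkey[drops$code == "DROP_DRUG"])
  out <- data.frame(date = estimates$date, tag = estimates$tag,
                    weight_g = estimates$grams, stringsAsFactors = FALSE)
  ekey <- key(out$tag, out$date)
  out$water_drops <- as.integer(ifelse(is.na(match(ekey, names(water))), 0L,
                                       water[match(ekey, names(water))]))
  out$drug_drops <- as.integer(ifelse(is.na(match(ekey, names(drug))), 0L,
                                      drug[match(ekey, names(drug))]))
  out$drug_ug <- out$drug_drops * ug_per_drop(config)
  out <- out[order(out$date, out$tag), , drop = FALSE]
  rownames(out) <- NULL
  out
}
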