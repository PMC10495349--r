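#' Read RFID perch-visit records
#'
#' Reads a CSV of per-second perch occupancy records with columns `tag_id`,
#' `day`, `feeder`, `perch`, `time` (non-negative integer seconds within the
#' session). Records are validated and returned time-sorted; the set of tag
#' ids present is attached as an attribute so unknown tags can be reported
#' downstream.
#'
#' @param path Path to the CSV file.
#' @return A time-sorted data.frame of visit records.
#' @export
read_visits <- function(path) {
  v <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("tag_id", "day", "feeder", "perch", "time")
  miss <- setdiff(required, names(v))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  tm <- suppressWarnings(as.integer(v$time))
  bad <- which(is.na(tm) | tm < 0)
  if (length(bad))
    stop("unparseable or negative timestamp at row ", bad[1])
  v$time <- tm
  v <- v[order(v$day, v$feeder, v$perch, v$tag_id, v$time), , drop = FALSE]
  rownames(v) <- NULL
  attr(v, "tags") <- sort(unique(v$tag_id))
  v
}

# Collapse per-second records into occupancy intervals [start, end) per
# (day, feeder, perch, tag): maximal runs of consecutive seconds.
visits_to_intervals <- function(visits) {
  if (nrow(visits) == 0)
    return(data.frame(tag_id = character(), day = integer(),
                      feeder = integer(), perch = integer(),
                      start = integer(), end = integer()))
  o <- order(visits$day, visits$feeder, visits$perch, visits$tag_id,
             visits$time)
  v <- visits[o, , drop = FALSE]
  key <- paste(v$day, v$feeder, v$perch, v$tag_id, sep = "\r")
  new_run <- c(TRUE, key[-1] != key[-nrow(v)] |
                 diff(v$time) != 1L)
  run <- cumsum(new_run)
  first <- which(new_run)
  last <- c(first[-1] - 1L, nrow(v))
  data.frame(tag_id = v$tag_id[first], day = v$day[first],
             feeder = v$feeder[first], perch = v$perch[first],
             start = v$time[first], end = v$time[last] + 1L,
             stringsAsFactors = FALSE)
}

#' Extract ordered dyadic association events from visit records
#'
#' An association event begins when both perches of a feeder unit are
#' occupied by distinct individuals and ends when either leaves (or is
#' replaced by another forager, which closes the event and opens a new
#' one). The first arrival within the ongoing occupancy bout is the
#' `source`, the joiner the `target`; simultaneous arrivals are broken
#' deterministically (lexicographically smaller id is the source).
#' Consecutive overlaps of the same dyad on the same feeder separated by at
#' most `gap_tolerance` seconds are merged into one event (bridging missed
#' RFID reads); the merged duration is the summed co-occupancy. Outcome is
#' `success` iff the two individuals share a treatment class.
#'
#' @param visits Visit records as returned by [read_visits()] (or the
#'   `visits` element of a [simulate_market()] result).
#' @param individuals Data frame with columns `id` and `class`.
#' @param affiliations Optional edge list (`id1`, `id2`, `relation`) used to
#'   flag affiliate dyads.
#' @param gap_tolerance Maximum gap in seconds bridged when merging
#'   same-dyad overlaps (default 2).
#' @param test_tags Character vector of test-tag ids removed before
#'   extraction.
#' @return Ordered data.frame of association events (one row per event,
#'   globally indexed by `(day, start_time)`).
#' @export
extract_events <- function(visits, individuals, affiliations = NULL,
                           gap_tolerance = 2, test_tags = NULL) {
  if (!is.null(test_tags))
    visits <- visits[!visits$tag_id %in% test_tags, , drop = FALSE]
  unknown <- setdiff(unique(visits$tag_id), individuals$id)
  if (length(unknown))
    stop("unknown tag id(s): ", paste(unknown, collapse = ", "))
  cls <- setNames(individuals$class, individuals$id)
  affkey <- character(0)
  if (!is.null(affiliations) && nrow(affiliations) > 0)
    affkey <- dyad_key(affiliations$id1, affiliations$id2)

  iv <- visits_to_intervals(visits)
  out <- list()
  for (grp in split(iv, list(iv$day, iv$feeder), drop = TRUE)) {
    day <- grp$day[1]; feeder <- grp$feeder[1]
    # reject physically impossible same-individual double occupancy
    for (id in unique(grp$tag_id)) {
      gi <- grp[grp$tag_id == id, , drop = FALSE]
      if (nrow(gi) > 1) {
        o <- order(gi$start)
        if (any(gi$start[o][-1] < gi$end[o][-nrow(gi)]))
          stop("individual ", id, " occupies two perches simultaneously (day ",
               day, ", feeder ", feeder, ")")
      }
    }
    perches <- sort(unique(grp$perch))
    if (length(perches) < 2) next
    a <- grp[grp$perch == perches[1], , drop = FALSE]
    b <- grp[grp$perch == perches[2], , drop = FALSE]
    if (nrow(a) == 0 || nrow(b) == 0) next
    ij <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
    st <- pmax(a$start[ij$i], b$start[ij$j])
    en <- pmin(a$end[ij$i], b$end[ij$j])
    keep <- en > st
    if (!any(keep)) next
    ij <- ij[keep, , drop = FALSE]; st <- st[keep]; en <- en[keep]
    id_a <- a$tag_id[ij$i]; id_b <- b$tag_id[ij$j]
    arr_a <- a$start[ij$i]; arr_b <- b$start[ij$j]
    src <- ifelse(arr_a < arr_b | (arr_a == arr_b & id_a < id_b), id_a, id_b)
    tgt <- ifelse(src == id_a, id_b, id_a)
    lat <- abs(arr_b - arr_a)
    o <- order(st)
    ev <- data.frame(day = day, apparatus = feeder,
                     source = src[o], target = tgt[o],
                     start_time = st[o], end_time = en[o],
                     arrival_latency = lat[o], duration = en[o] - st[o],
                     stringsAsFactors = FALSE)
    # merge same-dyad events separated by <= gap_tolerance
    if (nrow(ev) > 1) {
      dk <- dyad_key(ev$source, ev$target)
      merged <- logical(nrow(ev))
      for (k in 2:nrow(ev)) {
        # only the immediately preceding surviving event can absorb k
        prev <- max(which(!merged[seq_len(k - 1)]))
        if (dk[prev] == dk[k] && ev$start_time[k] - ev$end_time[prev] >= 0 &&
            ev$start_time[k] - ev$end_time[prev] <= gap_tolerance) {
          ev$end_time[prev] <- ev$end_time[k]
          ev$duration[prev] <- ev$duration[prev] + ev$duration[k]
          merged[k] <- TRUE
        }
      }
      ev <- ev[!merged, , drop = FALSE]
    }
    out[[length(out) + 1L]] <- ev
  }
  if (!length(out))
    return(empty_events())
  ev <- do.call(rbind, out)
  ev <- ev[order(ev$day, ev$start_time, ev$apparatus, ev$source), ,
           drop = FALSE]
  ev$index <- seq_len(nrow(ev))
  ev$outcome <- unname(ifelse(cls[ev$source] == cls[ev$target],
                              "success", "fail"))
  ev$is_same_class <- unname(cls[ev$source] == cls[ev$target])
  ev$is_affiliate <- dyad_key(ev$source, ev$target) %in% affkey
  rownames(ev) <- NULL
  ev[, c("index", "day", "apparatus", "source", "target", "start_time",
         "arrival_latency", "duration", "outcome", "is_same_class",
         "is_affiliate")]
}

dyad_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

empty_events <- function() {
  data.frame(index = integer(), day = integer(), apparatus = integer(),
             source = character(), target = character(),
             start_time = integer(), arrival_latency = integer(),
             duration = integer(), outcome = character(),
             is_same_class = logical(), is_affiliate = logical())
}

#' Write an event table as CSV
#'
#' Emits the event dialect (`index, day, feeder, source, target, start,
#' latency, duration, outcome`) bit-stably.
#'
#' @param events Event table as produced by [extract_events()].
#' @param path Output path.
#' @export
write_events <- function(events, path) {
  out <- data.frame(index = events$index, day = events$day,
                    feeder = events$apparatus, source = events$source,
                    target = events$target, start = events$start_time,
                    latency = events$arrival_latency,
                    duration = events$duration, outcome = events$outcome)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an event table written by [write_events()]
#'
#' @param path Path to the event CSV.
#' @param individuals Data frame with `id` and `class` (used to restore the
#'   class-match flag).
#' @param affiliations Optional affiliation edge list.
#' @return An event table in the same layout as [extract_events()].
#' @export
read_events <- function(path, individuals, affiliations = NULL) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("index", "day", "feeder", "source", "target", "start",
                "latency", "duration", "outcome")
  miss <- setdiff(required, names(x))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  cls <- setNames(individuals$class, individuals$id)
  affkey <- character(0)
  if (!is.null(affiliations) && nrow(affiliations) > 0)
    affkey <- dyad_key(affiliations$id1, affiliations$id2)
  data.frame(index = x$index, day = x$day, apparatus = x$feeder,
             source = x$source, target = x$target, start_time = x$start,
             arrival_latency = x$latency, duration = x$duration,
             outcome = x$outcome,
             is_same_class = unname(cls[x$source] == cls[x$target]),
             is_affiliate = dyad_key(x$source, x$target) %in% affkey,
             stringsAsFactors = FALSE)
}
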