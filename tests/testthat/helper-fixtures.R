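# Small in-code fixtures shared across test files.

make_individuals <- function(classes, entry_day = 1L) {
  n <- length(classes)
  data.frame(id = sprintf("I%02d", seq_len(n)), class = classes,
             entry_day = rep_len(entry_day, n), is_regular = FALSE,
             stringsAsFactors = FALSE)
}

# Build an event table by hand; outcome and flags derived from classes.
make_event_table <- function(source, target, individuals,
                             day = 1L, apparatus = 1L,
                             start = NULL, latency = 1L, duration = 10L,
                             affiliations = NULL) {
  n <- length(source)
  if (is.null(start)) start <- seq_len(n) * 100L
  cls <- stats::setNames(individuals$class, individuals$id)
  affkey <- character(0)
  if (!is.null(affiliations) && nrow(affiliations) > 0)
    affkey <- paste(pmin(affiliations$id1, affiliations$id2),
                    pmax(affiliations$id1, affiliations$id2), sep = "\r")
  key <- paste(pmin(source, target), pmax(source, target), sep = "\r")
  ev <- data.frame(index = seq_len(n), day = rep_len(day, n),
                   apparatus = rep_len(apparatus, n),
                   source = source, target = target,
                   start_time = start,
                   arrival_latency = rep_len(latency, n),
                   duration = rep_len(duration, n),
                   stringsAsFactors = FALSE)
  ev$outcome <- unname(ifelse(cls[source] == cls[target], "success", "fail"))
  ev$is_same_class <- unname(cls[source] == cls[target])
  ev$is_affiliate <- key %in% affkey
  ev
}

# Per-second visit rows for one occupancy interval [start, end).
visit_rows <- function(tag, day, feeder, perch, start, end) {
  data.frame(tag_id = tag, day = day, feeder = feeder, perch = perch,
             time = seq.int(start, end - 1L), stringsAsFactors = FALSE)
}
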