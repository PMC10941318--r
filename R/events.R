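#' Parameters for gathering-event detection
#'
#' @param hard_gap_s Pre-segmentation gap, seconds: consecutive reads at a
#'   feeder separated by more than this start a new segment before any
#'   mixture is fitted.
#' @param k_max Maximum number of Gaussian components per segment.
#' @param min_reads_per_event Events with fewer reads are merged into the
#'   nearest event in time at the same feeder.
#' @param seed Integer seed (the mixture fit is deterministic; the seed is
#'   retained so the full event stage is reproducible by contract).
#' @return List of class `event_params`.
#' @export
event_params <- function(hard_gap_s = 600, k_max = 15,
                         min_reads_per_event = 1, seed = 1L) {
  stopifnot(hard_gap_s > 0, k_max >= 1, min_reads_per_event >= 1)
  structure(list(hard_gap_s = hard_gap_s, k_max = k_max,
                 min_reads_per_event = min_reads_per_event,
                 seed = as.integer(seed)),
            class = "event_params")
}

#' Segment sorted timestamps by hard temporal gaps
#'
#' Consecutive reads separated by more than `hard_gap_s` fall in different
#' segments; the union of segments is the input. Increasing `hard_gap_s`
#' can only merge segments, never split them.
#'
#' @param timestamps Numeric vector, sorted ascending.
#' @param hard_gap_s Gap threshold in seconds (> 0).
#' @return A list of integer index vectors into `timestamps`, one per
#'   segment, in time order; empty input gives an empty list.
#' @export
segment_by_gaps <- function(timestamps, hard_gap_s) {
  stopifnot(hard_gap_s > 0)
  n <- length(timestamps)
  if (n == 0) return(list())
  if (is.unsorted(timestamps)) {
    stop("`timestamps` must be sorted ascending", call. = FALSE)
  }
  breaks <- which(diff(timestamps) > hard_gap_s)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, n)
  mapply(seq.int, starts, ends, SIMPLIFY = FALSE)
}

#' Fit a 1-D Gaussian mixture to read times within a segment
#'
#' Fits maximum-likelihood Gaussian mixtures with k = 1..min(`k_max`, n)
#' components (via \pkg{mclust}) and selects k by BIC; each read is
#' assigned to its maximum-responsibility component. Degenerate segments
#' (a single read, or all reads at the same second) return one component
#' with a variance floor of 1 s^2; the same floor is applied to any
#' fitted component.
#'
#' @param timestamps Numeric vector of read times (>= 1).
#' @param k_max Maximum number of components.
#' @param seed Unused placeholder for interface stability: the EM fit and
#'   its hierarchical initialisation are deterministic.
#' @param min_separation_s Floor on the separation of distinct
#'   components: after the fit, adjacent components are merged while
#'   their means are closer than `max(min_separation_s, 2 x` the smaller
#'   of their spreads`)` — overlapping modes are one gathering, and the
#'   variance prior can return duplicate components at essentially the
#'   same mean. The event detector sets this floor from its hard gap.
#' @return List with `k`, `means`, `sds`, `weights` (each length `k`) and
#'   `assignment` (integer component index per read).
#' @export
fit_time_mixture <- function(timestamps, k_max, seed = NULL,
                             min_separation_s = 2) {
  n <- length(timestamps)
  if (n < 1) stop("need at least one timestamp", call. = FALSE)
  single <- function() {
    list(k = 1L, means = mean(timestamps),
         sds = max(sd_or_zero(timestamps), 1), weights = 1,
         assignment = rep(1L, n))
  }
  if (n == 1 || diff(range(timestamps)) < .Machine$double.eps) {
    return(single())
  }
  gmax <- min(k_max, n)
  # the conjugate prior regularises component variances, which guards
  # against spurious near-zero-variance components on tied integer
  # timestamps
  fit <- suppressWarnings(tryCatch(
    mclust::Mclust(timestamps, G = seq_len(gmax), modelNames = "V",
                   prior = mclust::priorControl(), verbose = FALSE),
    error = function(e) NULL))
  if (is.null(fit)) {
    fit <- suppressWarnings(tryCatch(
      mclust::Mclust(timestamps, G = seq_len(gmax), modelNames = "V",
                     verbose = FALSE),
      error = function(e) NULL))
  }
  if (is.null(fit)) return(single())
  comp <- merge_overlapping_components(as.integer(fit$classification),
                                       timestamps, min_separation_s)
  # renumber in time order and summarise empirically
  centers <- sort(tapply(timestamps, comp, mean))
  relabel <- setNames(seq_along(centers), names(centers))
  comp <- unname(relabel[as.character(comp)])
  list(k = length(centers),
       means = unname(centers),
       sds = pmax(vapply(seq_along(centers), function(i) {
         sd_or_zero(timestamps[comp == i])
       }, 0), 1),
       weights = unname(as.vector(table(comp))) / n,
       assignment = comp)
}

sd_or_zero <- function(x) if (length(x) < 2) 0 else sd(x)

#' Detect gathering events in a detection stream
#'
#' Per feeder and deployment window: reads are segmented by hard temporal
#' gaps ([segment_by_gaps()]), a BIC-selected Gaussian mixture is fitted
#' to each segment ([fit_time_mixture()]), and each selected component
#' becomes one gathering event whose members are the unique tags among
#' its reads. Events with fewer than `min_reads_per_event` reads are
#' merged into the nearest event in time at the same feeder and window.
#' Reads falling outside every scheduled window for their feeder are
#' rejected and counted.
#'
#' @param detections Data frame with columns `tag_id`, `feeder_id`,
#'   `timestamp_s`.
#' @param schedule Schedule table with `window_label`, `season`,
#'   `feeder_id`, `start_s`, `end_s` (half-open windows).
#' @param params An [event_params()].
#' @return List of class `gathering_events` with `events` (data frame
#'   `event_id`, `window_label`, `season`, `feeder_id`, `start_s`,
#'   `end_s`, `n_reads`, `member_tags`), `reads` (accepted reads with
#'   their `event_id`), and `n_rejected`.
#' @export
detect_gathering_events <- function(detections, schedule,
                                    params = event_params()) {
  stopifnot(inherits(params, "event_params"))
  need <- c("tag_id", "feeder_id", "timestamp_s")
  if (!all(need %in% names(detections))) {
    stop("detections must have columns tag_id, feeder_id, timestamp_s",
         call. = FALSE)
  }
  det <- detections[, need]
  # assign each read to its window (half-open [start_s, end_s))
  det$window_label <- NA_character_
  det$season <- NA_character_
  sched <- schedule[order(schedule$start_s), ]
  for (r in seq_len(nrow(sched))) {
    w <- sched[r, ]
    hit <- det$feeder_id == w$feeder_id &
      det$timestamp_s >= w$start_s & det$timestamp_s < w$end_s
    det$window_label[hit] <- w$window_label
    det$season[hit] <- w$season
  }
  n_rejected <- sum(is.na(det$window_label))
  if (n_rejected > 0) {
    warning(sprintf("%d read(s) outside every scheduled window rejected",
                    n_rejected), call. = FALSE)
  }
  det <- det[!is.na(det$window_label), ]
  det <- det[order(det$feeder_id, det$timestamp_s, det$tag_id), ]
  rownames(det) <- NULL
  det$event_id <- NA_character_
  ev_rows <- list()
  counter <- 0
  if (nrow(det) > 0) {
    groups <- split(seq_len(nrow(det)),
                    list(det$window_label, det$feeder_id), drop = TRUE)
    # window-major, time-ordered event numbering
    ord <- order(vapply(groups, function(ix) min(det$timestamp_s[ix]), 0))
    for (g in groups[ord]) {
      ts <- det$timestamp_s[g]
      segs <- segment_by_gaps(ts, params$hard_gap_s)
      comp <- integer(length(g))
      n_comp <- 0
      for (sg in segs) {
        # visits closer than ~half the hard gap are not resolvable as
        # distinct gatherings at the timescale the gap defines, so cap
        # the component count by the segment's span
        cap <- 1 + ceiling(diff(range(ts[sg])) / (0.6 * params$hard_gap_s))
        mix <- fit_time_mixture(ts[sg], min(params$k_max, cap),
                                params$seed,
                                min_separation_s = 0.3 * params$hard_gap_s)
        comp[sg] <- n_comp + mix$assignment
        n_comp <- n_comp + mix$k
      }
      comp <- merge_small_components(comp, ts, params$min_reads_per_event)
      for (cid in sort(unique(comp))) {
        counter <- counter + 1
        eid <- sprintf("E%05d", counter)
        ix <- g[comp == cid]
        det$event_id[ix] <- eid
        ev_rows[[counter]] <- data.frame(
          event_id = eid,
          window_label = det$window_label[ix[1]],
          season = det$season[ix[1]],
          feeder_id = det$feeder_id[ix[1]],
          start_s = min(det$timestamp_s[ix]),
          end_s = max(det$timestamp_s[ix]),
          n_reads = length(ix),
          member_tags = paste(sort(unique(det$tag_id[ix])), collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  events <- if (length(ev_rows)) do.call(rbind, ev_rows) else
    data.frame(event_id = character(), window_label = character(),
               season = character(), feeder_id = character(),
               start_s = numeric(), end_s = numeric(),
               n_reads = integer(), member_tags = character(),
               stringsAsFactors = FALSE)
  events <- events[order(events$feeder_id, events$start_s), ]
  rownames(events) <- NULL
  structure(list(events = events, reads = det, n_rejected = n_rejected),
            class = "gathering_events")
}

# Merge adjacent components that are not meaningfully separated.
# Pairs closer than `min_sep` merge unconditionally (the detector's
# resolution floor); pairs within six spreads of each other are
# re-examined in isolation (screen: within four spreads) — if a single
# Gaussian explains their reads
# better than two (BIC, same variance-regularised fit), they are two
# slices of one gathering and merge.
merge_overlapping_components <- function(comp, ts, min_sep) {
  pair_prefers_one <- function(xs) {
    f <- suppressWarnings(tryCatch(
      mclust::Mclust(xs, G = 1:2, modelNames = "V",
                     prior = mclust::priorControl(), verbose = FALSE),
      error = function(e) NULL))
    !is.null(f) && f$G == 1
  }
  repeat {
    centers <- sort(tapply(ts, comp, mean))
    if (length(centers) < 2) return(comp)
    ids <- as.integer(names(centers))
    sds <- vapply(ids, function(k) sd_or_zero(ts[comp == k]), 0)
    gaps <- diff(centers)
    merged <- FALSE
    below <- which(gaps < min_sep)
    if (length(below) > 0) {
      i <- below[which.min(gaps[below])]
      comp[comp == ids[i + 1]] <- ids[i]
      merged <- TRUE
    } else {
      screen <- which(gaps < 4 * pmax(head(sds, -1), tail(sds, -1), 1))
      for (i in screen[order(gaps[screen])]) {
        xs <- ts[comp %in% ids[c(i, i + 1)]]
        if (length(xs) >= 4 && diff(range(xs)) > 0 &&
            pair_prefers_one(xs)) {
          comp[comp == ids[i + 1]] <- ids[i]
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) return(comp)
  }
}

# Reassign components with fewer than `min_reads` reads to the component
# whose mean read time is nearest; repeats until stable or one remains.
merge_small_components <- function(comp, ts, min_reads) {
  repeat {
    tab <- table(comp)
    small <- as.integer(names(tab)[tab < min_reads])
    if (length(small) == 0 || length(tab) == 1) return(comp)
    centers <- tapply(ts, comp, mean)
    ids <- as.integer(names(centers))
    for (s in small[1]) {
      others <- ids[ids != s]
      tgt <- others[which.min(abs(centers[as.character(others)] -
                                    centers[as.character(s)]))]
      comp[comp == s] <- tgt
    }
  }
}

#' Group-by-individual matrix
#'
#' Builds the binary membership table underlying the gambit-of-the-group
#' networks: one row per gathering event, one column per bird, cell 1 iff
#' the bird was a member of the event. Column sums are each bird's
#' distinct-group count (the quantity the inclusion filter thresholds);
#' row sums are group sizes.
#'
#' @param events A `gathering_events` object from
#'   [detect_gathering_events()], or a data frame shaped like its
#'   `events` element (including a latent event log from
#'   [simulate_detections()]).
#' @param birds Optional population table; if given, columns cover every
#'   bird (possibly with all-zero columns) and unknown tags error.
#' @return Binary matrix with `dimnames` (event IDs x tag IDs) and an
#'   `"events"` attribute holding the event metadata (`feeder_id`,
#'   `start_s`, `end_s`, `window_label`, `season` when available), used
#'   downstream to resolve time-overlapping groups.
#' @export
group_by_individual <- function(events, birds = NULL) {
  ev <- if (inherits(events, "gathering_events")) events$events else events
  stopifnot(is.data.frame(ev), "member_tags" %in% names(ev))
  members <- strsplit(ev$member_tags, ";", fixed = TRUE)
  tags <- sort(unique(unlist(members)))
  if (!is.null(birds)) {
    unknown <- setdiff(tags, birds$tag_id)
    if (length(unknown) > 0) {
      stop("tags not in bird table: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    tags <- birds$tag_id
  }
  m <- matrix(0L, nrow(ev), length(tags),
              dimnames = list(ev$event_id, tags))
  for (i in seq_along(members)) {
    m[i, members[[i]]] <- 1L
  }
  meta_cols <- intersect(c("event_id", "window_label", "season",
                           "feeder_id", "start_s", "end_s"), names(ev))
  attr(m, "events") <- ev[, meta_cols, drop = FALSE]
  m
}

#' Write a gathering-event table as delimited text
#'
#' @param events A `gathering_events` object or its `events` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  ev <- if (inherits(events, "gathering_events")) events$events else events
  out <- data.frame(event_id = ev$event_id, feeder_id = ev$feeder_id,
                    start_s = ev$start_s, end_s = ev$end_s,
                    n_members = lengths(strsplit(ev$member_tags, ";")),
                    member_tags = ev$member_tags)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Score detected gathering events against a latent event log
#'
#' Matches each latent (ground-truth) event to the detected event at the
#' same feeder whose time span is nearest its centre, and scores the
#' match as recovered when the detected member set equals the latent one
#' exactly and no other latent event matched that detected event first.
#' Used to validate the event detector on simulated streams.
#'
#' @param detected A `gathering_events` object or its `events` data
#'   frame.
#' @param latent Latent event log from [simulate_detections()].
#' @return List with `n_latent`, `n_detected`, `n_recovered` and
#'   `recovery_rate` (fraction of latent events recovered with exact
#'   member sets).
#' @export
event_recovery <- function(detected, latent) {
  det <- if (inherits(detected, "gathering_events")) detected$events else
    detected
  n_latent <- nrow(latent)
  recovered <- 0
  used <- character(0)
  for (f in unique(latent$feeder_id)) {
    lat_f <- latent[latent$feeder_id == f, ]
    det_f <- det[det$feeder_id == f, ]
    if (nrow(det_f) == 0) next
    for (i in seq_len(nrow(lat_f))) {
      ce <- lat_f$center_s[i]
      d <- pmax(det_f$start_s - ce, 0) + pmax(ce - det_f$end_s, 0)
      j <- which.min(d)
      if (det_f$event_id[j] %in% used) next
      if (identical(det_f$member_tags[j], lat_f$member_tags[i])) {
        recovered <- recovered + 1
        used <- c(used, det_f$event_id[j])
      }
    }
  }
  list(n_latent = n_latent, n_detected = nrow(det),
       n_recovered = recovered,
       recovery_rate = if (n_latent > 0) recovered / n_latent else NA_real_)
}
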