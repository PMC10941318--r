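#' Configuration for the synthetic study world
#'
#' Bundles every knob of the synthetic-data generator: the breeding
#' population, the feeder array and deployment calendar, the latent social
#' structure, and the detection process. Defaults emulate a woodland
#' great-tit study: ~43 occupied nest boxes each fledging a clutch of ~6.5
#' nestlings, six RFID feeders deployed simultaneously for one 48-h period
#' per week across 14 spring-summer weeks, then three 48-h deployments in
#' each of autumn, winter and the following spring.
#'
#' @param n_nest_boxes Number of occupied nest boxes (each contributes one
#'   breeding pair of adults plus a clutch of nestlings).
#' @param mean_clutch_size Mean eggs laid per box (the species lays ~6.5
#'   on average).
#' @param nestling_survival Fraction of eggs that survive to day-15
#'   tagging; tagged-brood sizes are Poisson draws with mean
#'   `mean_clutch_size x nestling_survival`, truncated at 1. The
#'   default reproduces ~185 tagged nestlings across 43 boxes.
#' @param n_feeders Number of RFID feeders.
#' @param n_weekly_deployments Number of weekly 48-h deployments in the
#'   spring-summer period.
#' @param deployment_duration_h Duration of one deployment, hours.
#' @param seasonal_deployments_per_season Deployments pooled into each
#'   later-season network (autumn, winter, spring).
#' @param event_rate Gathering events per feeder-hour.
#' @param detection_rate Expected antenna reads per attendee per event
#'   (every attendee emits at least one read).
#' @param preference_params Named list of positive multipliers on the
#'   latent co-foraging propensity by relationship class (`sibling`,
#'   `parent`, `peer`, `other_adult`) plus `familiarity_carryover`, the
#'   [0, 1] weight with which a season's preference structure persists
#'   into the next season (1 = identical structure, 0 = drawn afresh).
#' @param home_range_concentration Total Dirichlet concentration of each
#'   bird's per-feeder home range (drawn independently per bird); larger
#'   values give flatter ranges, smaller values feeder specialists.
#' @param mortality_dispersal_rate Per-season-boundary probability that a
#'   bird is removed (death or dispersal) and emits no further reads.
#' @param recruitment_scale Expected number of recruited attendees per
#'   event beyond the seed bird; recruitment probability is allocated
#'   across birds proportionally to `preference x home-range weight` and
#'   capped at 0.95, so typical flock sizes stay stable as the
#'   population grows.
#' @param event_spread_s Standard deviation, in seconds, of read times
#'   around an event's centre.
#' @param min_spacing_factor Minimum spacing between event centres at one
#'   feeder, as a multiple of `event_spread_s`; arrivals closer than this
#'   are thinned so planted events stay recoverable.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A list of class `world_config`.
#' @export
world_config <- function(n_nest_boxes = 43,
                         mean_clutch_size = 6.5,
                         nestling_survival = 0.66,
                         n_feeders = 6,
                         n_weekly_deployments = 14,
                         deployment_duration_h = 48,
                         seasonal_deployments_per_season = 3,
                         event_rate = 4,
                         detection_rate = 3,
                         preference_params = list(sibling = 2.5,
                                                  parent = 1.5,
                                                  peer = 1.5,
                                                  other_adult = 1,
                                                  familiarity_carryover = 0.75),
                         home_range_concentration = 6,
                         mortality_dispersal_rate = 0.15,
                         recruitment_scale = 3,
                         event_spread_s = 60,
                         min_spacing_factor = 5,
                         seed = 1L) {
  cfg <- list(n_nest_boxes = n_nest_boxes,
              mean_clutch_size = mean_clutch_size,
              nestling_survival = nestling_survival,
              n_feeders = n_feeders,
              n_weekly_deployments = n_weekly_deployments,
              deployment_duration_h = deployment_duration_h,
              seasonal_deployments_per_season = seasonal_deployments_per_season,
              event_rate = event_rate,
              detection_rate = detection_rate,
              preference_params = preference_params,
              home_range_concentration = home_range_concentration,
              mortality_dispersal_rate = mortality_dispersal_rate,
              recruitment_scale = recruitment_scale,
              event_spread_s = event_spread_s,
              min_spacing_factor = min_spacing_factor,
              seed = seed)
  validate_world_config(cfg)
  class(cfg) <- "world_config"
  cfg
}

validate_world_config <- function(cfg) {
  counts <- c("n_nest_boxes", "n_feeders", "n_weekly_deployments",
              "seasonal_deployments_per_season")
  for (f in counts) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] < 1) {
      stop(sprintf("`%s` must be a count >= 1", f), call. = FALSE)
    }
  }
  if (cfg$mean_clutch_size <= 0) {
    stop("`mean_clutch_size` must be positive", call. = FALSE)
  }
  if (cfg$nestling_survival <= 0 || cfg$nestling_survival > 1) {
    stop("`nestling_survival` must lie in (0, 1]", call. = FALSE)
  }
  rates <- c("event_rate", "detection_rate", "mortality_dispersal_rate")
  for (f in rates) {
    if (cfg[[f]] < 0) stop(sprintf("`%s` must be >= 0", f), call. = FALSE)
  }
  pp <- cfg$preference_params
  mult <- c("sibling", "parent", "peer", "other_adult")
  if (!all(mult %in% names(pp))) {
    stop("`preference_params` must name sibling, parent, peer, other_adult",
         call. = FALSE)
  }
  if (any(unlist(pp[mult]) <= 0)) {
    stop("preference multipliers must be > 0", call. = FALSE)
  }
  co <- pp$familiarity_carryover
  if (is.null(co) || co < 0 || co > 1) {
    stop("`familiarity_carryover` must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$home_range_concentration <= 0) {
    stop("`home_range_concentration` must be > 0", call. = FALSE)
  }
  invisible(cfg)
}

#' Deployment schedule for a synthetic world
#'
#' One row per deployment window and feeder. Feeders are deployed
#' simultaneously, so all feeders share each window's half-open interval
#' `[start_s, end_s)`. Day 0 of the study clock is the start of the first
#' weekly deployment; weekly windows open every 7 days, and the three
#' later seasons open in weeks 20-22 (autumn), 33-35 (winter) and 46-48
#' (spring).
#'
#' @param config A [world_config()].
#' @return Data frame with columns `window_label`, `season`,
#'   `feeder_id`, `start_s`, `end_s`, `start_day`.
#' @export
build_schedule <- function(config) {
  day_s <- 86400
  dur <- config$deployment_duration_h * 3600
  rows <- list()
  for (i in seq_len(config$n_weekly_deployments)) {
    start_day <- 7 * (i - 1)
    rows[[length(rows) + 1]] <- data.frame(
      window_label = sprintf("week-%02d", i),
      season = "summer",
      start_s = start_day * day_s,
      end_s = start_day * day_s + dur,
      start_day = start_day)
  }
  season_week0 <- c(autumn = 19, winter = 32, spring = 45)
  for (season in names(season_week0)) {
    for (j in seq_len(config$seasonal_deployments_per_season)) {
      start_day <- 7 * (season_week0[[season]] + j - 1)
      rows[[length(rows) + 1]] <- data.frame(
        window_label = sprintf("%s-%d", season, j),
        season = season,
        start_s = start_day * day_s,
        end_s = start_day * day_s + dur,
        start_day = start_day)
    }
  }
  sched <- do.call(rbind, rows)
  feeders <- feeder_ids(config$n_feeders)
  out <- merge(sched, data.frame(feeder_id = feeders), by = NULL)
  out <- out[order(out$start_s, out$feeder_id),
             c("window_label", "season", "feeder_id",
               "start_s", "end_s", "start_day")]
  rownames(out) <- NULL
  out
}

feeder_ids <- function(n) sprintf("F%d", seq_len(n))

#' Generate a breeding population with pedigree
#'
#' Creates one breeding pair of adults per occupied nest box plus a clutch
#' of PIT-tagged nestlings per box. Clutch sizes are Poisson draws
#' (truncated at one) around `mean_clutch_size`. Nestlings carry their
#' natal box, both parent IDs, hatch and fledge dates (fledging 22 days
#' after hatching) and a fledge weight drawn log-normally around 18 g.
#' Dates are integer days on the study clock (day 0 = first deployment);
#' broods hatch in the weeks before feeders first open.
#'
#' @param config A [world_config()].
#' @return Data frame with columns `tag_id`, `age_class`, `hatch_date`,
#'   `fledge_date`, `fledge_weight_g`, `natal_box`, `mother_id`,
#'   `father_id`. Adults have `NA` dates, weight and parents.
#' @export
generate_population <- function(config) {
  validate_world_config(config)
  with_seed(stage_seed(config$seed, "population"), {
    nb <- config$n_nest_boxes
    boxes <- sprintf("B%02d", seq_len(nb))
    mothers <- sprintf("AF%03d", seq_len(nb))
    fathers <- sprintf("AM%03d", seq_len(nb))
    adults <- data.frame(
      tag_id = c(mothers, fathers),
      age_class = "adult",
      hatch_date = NA_integer_,
      fledge_date = NA_integer_,
      fledge_weight_g = NA_real_,
      natal_box = NA_character_,
      mother_id = NA_character_,
      father_id = NA_character_,
      stringsAsFactors = FALSE)
    # tagged-brood sizes: truncated Poisson (redraw zeros) around
    # eggs x survival-to-tagging
    mu <- config$mean_clutch_size * config$nestling_survival
    clutch <- rpois(nb, mu)
    while (any(clutch == 0)) {
      clutch[clutch == 0] <- rpois(sum(clutch == 0), mu)
    }
    hatch <- round(rnorm(nb, mean = -25, sd = 4))
    nest_rows <- vector("list", nb)
    k <- 0
    for (b in seq_len(nb)) {
      ids <- sprintf("JV%03d", k + seq_len(clutch[b]))
      k <- k + clutch[b]
      nest_rows[[b]] <- data.frame(
        tag_id = ids,
        age_class = "first_year",
        hatch_date = hatch[b],
        fledge_date = hatch[b] + 22L,
        fledge_weight_g = round(rlnorm(clutch[b], log(18), 0.08), 1),
        natal_box = boxes[b],
        mother_id = mothers[b],
        father_id = fathers[b],
        stringsAsFactors = FALSE)
    }
    adults$natal_box <- NA_character_
    birds <- rbind(adults, do.call(rbind, nest_rows))
    # adults of a box are recorded as its breeding pair
    birds$box_of_pair <- NA_character_
    birds$box_of_pair[match(mothers, birds$tag_id)] <- boxes
    birds$box_of_pair[match(fathers, birds$tag_id)] <- boxes
    rownames(birds) <- NULL
    birds
  })
}

# Relationship class for every ordered pair of birds: "parents" if the
# partner is the focal's recorded mother or father (or vice versa),
# "siblings" if both parents are shared, "peers" for other first-year
# pairs, "other_adults" otherwise.  Symmetric by construction.
relationship_matrix <- function(birds) {
  n <- nrow(birds)
  ids <- birds$tag_id
  rel <- matrix("other_adults", n, n, dimnames = list(ids, ids))
  juv <- birds$age_class == "first_year"
  rel[juv, juv] <- "peers"
  mo <- birds$mother_id
  fa <- birds$father_id
  same_mo <- outer(mo, mo, function(a, b) !is.na(a) & !is.na(b) & a == b)
  same_fa <- outer(fa, fa, function(a, b) !is.na(a) & !is.na(b) & a == b)
  rel[same_mo & same_fa] <- "siblings"
  is_parent <- outer(ids, mo, "==") | outer(ids, fa, "==")
  is_parent[is.na(is_parent)] <- FALSE
  rel[is_parent | t(is_parent)] <- "parents"
  diag(rel) <- NA_character_
  rel
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g <- rep(1, length(alpha))
  g / sum(g)
}

#' Sample the latent social structure of a synthetic world
#'
#' Draws, for each season, a per-bird home range (a probability vector
#' over feeders, an independent Dirichlet draw per bird — space use is
#' deliberately independent of pedigree so that relationship effects
#' on association are identifiable net of space) and a
#' symmetric dyadic co-foraging preference matrix
#' `preference(i, j) = multiplier(relationship) x home-range similarity`,
#' where the similarity kernel is the Bhattacharyya coefficient between
#' the two home ranges. Between
#' consecutive seasons both components persist with weight
#' `familiarity_carryover` and are replaced by fresh draws with weight
#' `1 - familiarity_carryover`; birds are also removed at each season
#' boundary with probability `mortality_dispersal_rate`.
#'
#' @param birds Population table from [generate_population()].
#' @param config A [world_config()].
#' @return A list of class `social_structure` with elements `seasons`
#'   (character), `preference` and `home_range` (one matrix per season),
#'   `alive` (one logical vector per season), and `relationship` (the
#'   pairwise class matrix).
#' @export
sample_social_structure <- function(birds, config) {
  validate_world_config(config)
  n <- nrow(birds)
  ids <- birds$tag_id
  rel <- relationship_matrix(birds)
  pp <- config$preference_params
  mult <- matrix(1, n, n, dimnames = list(ids, ids))
  mult[rel == "siblings"] <- pp$sibling
  mult[rel == "parents"] <- pp$parent
  mult[rel == "peers"] <- pp$peer
  mult[rel == "other_adults"] <- pp$other_adult
  seasons <- c("summer", "autumn", "winter", "spring")
  with_seed(stage_seed(config$seed, "structure"), {
    nf <- config$n_feeders
    draw_home_ranges <- function() {
      alpha <- rep(config$home_range_concentration / nf, nf)
      hr <- t(vapply(seq_len(n), function(i) rdirichlet1(alpha),
                     numeric(nf)))
      dimnames(hr) <- list(ids, feeder_ids(nf))
      hr
    }
    pref_from <- function(hr) {
      kern <- sqrt(hr) %*% t(sqrt(hr))
      p <- mult * kern
      diag(p) <- 0
      dimnames(p) <- list(ids, ids)
      p
    }
    carry <- pp$familiarity_carryover
    home_range <- preference <- alive <- vector("list", length(seasons))
    names(home_range) <- names(preference) <- names(alive) <- seasons
    hr <- draw_home_ranges()
    pref <- pref_from(hr)
    cur_alive <- rep(TRUE, n)
    for (s in seq_along(seasons)) {
      if (s > 1) {
        if (carry < 1) {
          hr_new <- carry * hr + (1 - carry) * draw_home_ranges()
          pref <- carry * pref + (1 - carry) * pref_from(hr_new)
          hr <- hr_new / rowSums(hr_new)
        }
        cur_alive <- cur_alive &
          (runif(n) >= config$mortality_dispersal_rate)
      }
      home_range[[s]] <- hr
      preference[[s]] <- pref
      alive[[s]] <- setNames(cur_alive, ids)
    }
    structure(list(seasons = seasons, preference = preference,
                   home_range = home_range, alive = alive,
                   relationship = rel),
              class = "social_structure")
  })
}

#' Simulate an RFID detection stream with a latent event log
#'
#' For each deployment window and feeder, gathering events arrive as a
#' Poisson process at `event_rate` events per hour, thinned so that
#' consecutive event centres are at least `min_spacing_factor x
#' event_spread_s` apart. Each event draws a seed attendee in proportion
#' to home-range weight at that feeder; every other living bird joins
#' with probability proportional to `preference(seed, j) x
#' home_range(j, feeder)`, scaled to recruit `recruitment_scale` birds
#' in expectation (capped at 0.95). Each attendee emits `1 + Poisson(detection_rate
#' - 1)` reads at integer seconds drawn Normal(event centre,
#' `event_spread_s`), clamped into the window. The latent event log
#' records the true membership of every event, which downstream recovery
#' tests treat as ground truth.
#'
#' @param birds Population table from [generate_population()].
#' @param social Structure from [sample_social_structure()].
#' @param config A [world_config()].
#' @param schedule Optional schedule; defaults to [build_schedule()].
#' @return List with `detections` (data frame `tag_id`, `feeder_id`,
#'   `timestamp_s`, plus the generating `event_id` for validation),
#'   `events` (latent log: `event_id`, `window_label`, `season`,
#'   `feeder_id`, `center_s`, `member_tags` as a `;`-joined string) and
#'   `schedule`.
#' @export
simulate_detections <- function(birds, social, config, schedule = NULL) {
  validate_world_config(config)
  if (is.null(schedule)) schedule <- build_schedule(config)
  ids <- birds$tag_id
  n <- length(ids)
  if (n == 0) {
    return(list(detections = empty_detections(), events = empty_event_log(),
                schedule = schedule))
  }
  stopifnot(identical(rownames(social$preference[[1]]), ids))
  min_gap <- config$min_spacing_factor * config$event_spread_s
  with_seed(stage_seed(config$seed, "detections"), {
    det <- list()
    evlog <- list()
    ev_counter <- 0
    for (r in seq_len(nrow(schedule))) {
      win <- schedule[r, ]
      season <- win$season
      alive <- social$alive[[season]]
      if (!any(alive)) next
      hr_f <- social$home_range[[season]][, win$feeder_id]
      pref <- social$preference[[season]]
      dur_s <- win$end_s - win$start_s
      n_ev <- rpois(1, config$event_rate * dur_s / 3600)
      if (n_ev == 0) next
      centers <- sort(win$start_s + runif(n_ev, 0, dur_s))
      keep <- c(TRUE, diff(centers) >= min_gap)
      while (!all(keep)) {  # re-thin: removal can create new close pairs
        centers <- centers[keep]
        keep <- c(TRUE, diff(centers) >= min_gap)
      }
      seed_w <- hr_f * alive
      if (sum(seed_w) == 0) next
      for (ce in centers) {
        ev_counter <- ev_counter + 1
        eid <- sprintf("L%05d", ev_counter)
        seed_bird <- sample.int(n, 1, prob = seed_w)
        w_j <- pref[seed_bird, ] * hr_f
        w_j[!alive] <- 0
        w_j[seed_bird] <- 0
        join_p <- if (sum(w_j) > 0) {
          pmin(0.95, config$recruitment_scale * w_j / sum(w_j))
        } else w_j
        members <- c(seed_bird, which(runif(n) < join_p))
        reads <- lapply(members, function(m) {
          k <- 1 + rpois(1, max(0, config$detection_rate - 1))
          ts <- round(rnorm(k, ce, config$event_spread_s))
          ts <- pmin(pmax(ts, win$start_s), win$end_s - 1)
          data.frame(tag_id = ids[m], feeder_id = win$feeder_id,
                     timestamp_s = as.integer(ts), event_id = eid,
                     stringsAsFactors = FALSE)
        })
        det[[length(det) + 1]] <- do.call(rbind, reads)
        evlog[[length(evlog) + 1]] <- data.frame(
          event_id = eid, window_label = win$window_label, season = season,
          feeder_id = win$feeder_id, center_s = ce,
          member_tags = paste(sort(ids[members]), collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
    detections <- if (length(det)) do.call(rbind, det) else empty_detections()
    detections <- detections[order(detections$timestamp_s,
                                   detections$feeder_id,
                                   detections$tag_id), ]
    rownames(detections) <- NULL
    events <- if (length(evlog)) do.call(rbind, evlog) else empty_event_log()
    list(detections = detections, events = events, schedule = schedule)
  })
}

empty_detections <- function() {
  data.frame(tag_id = character(), feeder_id = character(),
             timestamp_s = integer(), event_id = character(),
             stringsAsFactors = FALSE)
}

empty_event_log <- function() {
  data.frame(event_id = character(), window_label = character(),
             season = character(), feeder_id = character(),
             center_s = numeric(), member_tags = character(),
             stringsAsFactors = FALSE)
}

#' Write and read synthetic-world artefacts
#'
#' Detections and bird tables are plain delimited text with a single
#' header row; the latent event log is JSON-lines (one event object per
#' line).
#'
#' @param x Object to write.
#' @param path File path.
#' @name world_io
#' @return `write_*` return `path` invisibly; `read_detections` returns a
#'   validated detections data frame.
NULL

#' @rdname world_io
#' @export
write_detections <- function(x, path) {
  write.csv(x[, c("tag_id", "feeder_id", "timestamp_s")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname world_io
#' @export
write_birds <- function(x, path) {
  cols <- c("tag_id", "age_class", "hatch_date", "fledge_date",
            "fledge_weight_g", "natal_box", "mother_id", "father_id")
  write.csv(x[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname world_io
#' @export
write_event_log <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    writeLines(jsonlite::toJSON(as.list(x[i, ]), auto_unbox = TRUE), con)
  }
  invisible(path)
}
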