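#' Load a detection stream from delimited text
#'
#' Expects a header `tag_id,feeder_id,timestamp_s`. Malformed lines
#' (wrong field count, unparseable timestamp) are dropped and reported
#' with their line numbers.
#'
#' @param path CSV file path.
#' @return Validated detections data frame; attribute `"rejected_lines"`
#'   holds the 1-based line numbers of dropped lines.
#' @export
load_detections <- function(path) {
  raw <- readLines(path)
  if (length(raw) == 0) stop("empty file: ", path, call. = FALSE)
  header <- strsplit(raw[1], ",", fixed = TRUE)[[1]]
  need <- c("tag_id", "feeder_id", "timestamp_s")
  if (!all(need %in% header)) {
    stop("missing column(s): ", paste(setdiff(need, header), collapse = ", "),
         call. = FALSE)
  }
  parts <- strsplit(raw[-1], ",", fixed = TRUE)
  ok_len <- lengths(parts) == length(header)
  ts_ix <- match("timestamp_s", header)
  ts <- suppressWarnings(vapply(parts, function(p) {
    if (length(p) == length(header)) as.numeric(p[ts_ix]) else NA_real_
  }, 0))
  ok <- ok_len & !is.na(ts)
  rejected <- which(!ok) + 1L
  if (length(rejected) > 0) {
    warning(sprintf("rejected %d malformed line(s): %s",
                    length(rejected),
                    paste(head(rejected, 10), collapse = ", ")),
            call. = FALSE)
  }
  keep <- parts[ok]
  det <- data.frame(
    tag_id = vapply(keep, `[`, "", match("tag_id", header)),
    feeder_id = vapply(keep, `[`, "", match("feeder_id", header)),
    timestamp_s = ts[ok],
    stringsAsFactors = FALSE)
  attr(det, "rejected_lines") <- rejected
  det
}

#' Study configuration
#'
#' Collects the settings of a full study run: event-detection
#' parameters, the inclusion threshold, per-model MCMC specifications,
#' the permutation count for the assortativity tests and the global
#' seed. Model specs default to the study design: Model 1 (relationship
#' x age), 4 chains, 4000 iterations (2000 warm-up); Models 2, 3a, 3b
#' and 5a-c, 4 chains, 6000 iterations (3000 warm-up).
#'
#' @param events An [event_params()].
#' @param min_groups Inclusion filter threshold (default 5 distinct
#'   groups).
#' @param n_perm Node permutations per assortativity test (default
#'   1000).
#' @param models Named list of [zib_model_spec()]s for `model1`,
#'   `model2`, `model3a`, `model3b`, `model5`; missing entries get the
#'   defaults above.
#' @param overlap_method Space-use overlap covariate: `"proportion"`
#'   (share of the focal bird's reads at feeders the partner also used)
#'   or `"min_share"` (summed feeder-wise minimum of the two normalised
#'   usage profiles, a continuous symmetric similarity). See
#'   [space_overlap()].
#' @param seed Global seed; stage seeds are derived from it.
#' @return List of class `study_config`.
#' @export
study_config <- function(events = event_params(),
                         min_groups = 5,
                         n_perm = 1000,
                         models = list(),
                         overlap_method = c("proportion", "min_share"),
                         seed = 1L) {
  defaults <- default_model_specs(seed)
  defaults[names(models)] <- models
  structure(list(events = events, min_groups = min_groups,
                 n_perm = n_perm, models = defaults,
                 overlap_method = match.arg(overlap_method),
                 seed = as.integer(seed)),
            class = "study_config")
}

default_model_specs <- function(seed) {
  ms <- stage_seed(seed, "model")
  list(
    model1 = zib_model_spec(
      fixed_terms = c("relationship", "overlap", "focal_age_days"),
      interactions = list(c("relationship", "focal_age_days")),
      chains = 4, iterations = 4000, warmup = 2000, seed = ms),
    model2 = zib_model_spec(
      fixed_terms = c("weight_diff_std", "age_diff_std", "overlap",
                      "focal_age_days"),
      interactions = list(c("weight_diff_std", "focal_age_days"),
                          c("age_diff_std", "focal_age_days")),
      chains = 4, iterations = 6000, warmup = 3000, seed = ms + 1L),
    model3a = zib_model_spec(
      fixed_terms = c("parental_assoc_cum", "overlap", "focal_age_days"),
      interactions = list(c("parental_assoc_cum", "focal_age_days")),
      chains = 4, iterations = 6000, warmup = 3000, seed = ms + 2L),
    model3b = zib_model_spec(
      fixed_terms = c("parental_assoc_cum", "overlap", "focal_age_days"),
      interactions = list(c("parental_assoc_cum", "focal_age_days")),
      chains = 4, iterations = 6000, warmup = 3000, seed = ms + 3L),
    model5 = zib_model_spec(
      fixed_terms = c("prev_season_sri", "overlap", "focal_age_class"),
      interactions = list(c("prev_season_sri", "focal_age_class")),
      chains = 4, iterations = 6000, warmup = 3000, seed = ms + 4L))
}

# Weekly (or per-deployment) membership tables and networks.
window_memberships <- function(ev, windows) {
  lapply(setNames(windows, windows), function(w) {
    group_by_individual(ev$events[ev$events$window_label == w, ,
                                  drop = FALSE])
  })
}

window_profiles <- function(detections, schedule, window, birds, feeders) {
  sch <- schedule[schedule$window_label == window, ]
  keep <- rep(FALSE, nrow(detections))
  for (r in seq_len(nrow(sch))) {
    keep <- keep | (detections$feeder_id == sch$feeder_id[r] &
                      detections$timestamp_s >= sch$start_s[r] &
                      detections$timestamp_s < sch$end_s[r])
  }
  feeder_profiles(detections[keep, ], birds, feeders)
}

#' Run the ontogeny analyses (weekly networks; Models 1, 2, 3a, 3b)
#'
#' Builds one SRI network per weekly 48-h deployment (inclusion filter
#' applied per window), assembles the four spring-summer dyad tables and
#' fits their zero-inflated beta multi-membership models: Model 1
#' (relationship type x age, juvenile focal, all partners), Model 2
#' (homophily among peers, both directions), Model 3a (cumulative
#' association between partner adult and the focal's parents) and Model
#' 3b (cumulative association between the two juveniles' parents).
#' Cumulative parental covariates at week t pool weeks 1..t. Ages are
#' centered and homophily differences standardised within each full
#' table; the transforms are recorded in the run log.
#'
#' @param detections Detection data frame.
#' @param birds Population table.
#' @param schedule Schedule table (summer rows define the weekly
#'   windows).
#' @param config A [study_config()].
#' @param fit_models Set FALSE to stop after table assembly (useful for
#'   inspecting covariates).
#' @param which_models Subset of `c("model1", "model2", "model3a",
#'   "model3b")` to assemble and fit (default all four).
#' @return List with `networks`, `tables`, `fits`, `summaries`,
#'   `vif`, and `log`.
#' @export
run_ontogeny_analysis <- function(detections, birds, schedule,
                                  config = study_config(),
                                  fit_models = TRUE,
                                  which_models = c("model1", "model2",
                                                   "model3a", "model3b")) {
  ev <- detect_gathering_events(detections, schedule, config$events)
  summer <- schedule[schedule$season == "summer", ]
  windows <- unique(summer$window_label[order(summer$start_s)])
  feeders <- sort(unique(schedule$feeder_id))
  gbis <- window_memberships(ev, windows)
  networks <- list()
  tables1 <- tables2 <- tables3a <- tables3b <- list()
  log <- list(filter = list())
  week_days <- setNames(summer$start_day[match(windows,
                                               summer$window_label)],
                        windows)
  for (w in windows) {
    gbi <- gbis[[w]]
    if (nrow(gbi) == 0) next
    net <- suppressWarnings(build_network(gbi, w, config$min_groups))
    log$filter[[w]] <- c(birds_in = ncol(gbi),
                         birds_retained = length(net$birds))
    if (length(net$birds) < 2) next
    networks[[w]] <- net
    prof <- window_profiles(detections, schedule, w, net$birds, feeders)
    wd <- week_days[[w]]
    if (any(birds$age_class[match(net$birds, birds$tag_id)] ==
            "first_year")) {
      if ("model1" %in% which_models) {
        tables1[[w]] <- enumerate_dyads(net, birds, "juvenile_focal",
                                        "all", profiles = prof,
                                        window_day = wd,
                                        overlap_method =
                                          config$overlap_method)
      }
      t3a <- if (any(c("model3a") %in% which_models)) {
        enumerate_dyads(net, birds, "juvenile_focal",
                        "nonparent_adults", profiles = prof,
                        window_day = wd,
                        overlap_method = config$overlap_method)
      } else NULL
      t2 <- if (any(c("model2", "model3b") %in% which_models)) {
        enumerate_dyads(net, birds, "both_directions", "peers",
                        profiles = prof, window_day = wd,
                        overlap_method = config$overlap_method)
      } else NULL
      if (any(c("model3a", "model3b") %in% which_models)) {
        wk_ix <- seq_len(match(w, windows))
        # one unfiltered cumulative network over weeks 1..t; the
        # parental covariates are then all-pairs lookups in its SRI
        # matrix
        cum_pool <- if (length(wk_ix) == 1) gbis[[1]] else
          pool_deployments(gbis[wk_ix])
        cum_net <- suppressWarnings(
          build_network(cum_pool, paste0("cum-", w), min_groups = 1))
      }
      if (!is.null(t3a) && nrow(t3a) > 0) {
        t3a$parental_assoc_cum <- parental_assoc_from_net(
          cum_net, t3a$focal_id, t3a$partner_id, "adult", birds)
        tables3a[[w]] <- t3a
      }
      if (!is.null(t2) && nrow(t2) > 0) {
        if ("model2" %in% which_models) tables2[[w]] <- t2
        if ("model3b" %in% which_models) {
          t3b <- t2
          t3b$parental_assoc_cum <- parental_assoc_from_net(
            cum_net, t3b$focal_id, t3b$partner_id, "peer", birds)
          tables3b[[w]] <- t3b
        }
      }
    }
  }
  tables <- list()
  if ("model1" %in% which_models) {
    if (length(tables1) == 0) {
      stop("no juveniles retained in any weekly network", call. = FALSE)
    }
    tab1 <- do.call(rbind, tables1)
    tab1$focal_age_days <- as.numeric(
      center_and_standardize(tab1$focal_age_days, "center"))
    tables$model1 <- tab1
  }
  if (length(tables2) > 0) {
    tab2 <- do.call(rbind, tables2)
    tab2$weight_diff_std <- as.numeric(
      center_and_standardize(tab2$weight_diff, "zscore"))
    tab2$age_diff_std <- if (length(unique(tab2$age_diff)) > 1) {
      as.numeric(center_and_standardize(tab2$age_diff, "zscore"))
    } else 0 * tab2$age_diff  # single shared hatch date
    tab2$focal_age_days <- as.numeric(
      center_and_standardize(tab2$focal_age_days, "center"))
    tables$model2 <- tab2
  }
  finish3 <- function(lst) {
    if (length(lst) == 0) return(NULL)
    tb <- do.call(rbind, lst)
    n_flagged <- sum(is.na(tb$parental_assoc_cum))
    tb <- tb[!is.na(tb$parental_assoc_cum), ]
    tb$focal_age_days <- as.numeric(
      center_and_standardize(tb$focal_age_days, "center"))
    attr(tb, "n_excluded_no_parents") <- n_flagged
    tb
  }
  tables$model3a <- finish3(tables3a)
  tables$model3b <- finish3(tables3b)
  fits <- list()
  summaries <- list()
  vifs <- list()
  if (fit_models) {
    for (mn in names(tables)) {
      tb <- tables[[mn]]
      if (is.null(tb) || nrow(tb) < 20) next
      spec_name <- if (mn %in% c("model3a", "model3b")) mn else mn
      spec <- config$models[[spec_name]]
      vifs[[mn]] <- vif_for_spec(tb, spec)
      fits[[mn]] <- fit_zib_mm(tb, spec)
      summaries[[mn]] <- summarize_odds_ratios(fits[[mn]])
    }
  }
  log$n_rejected_reads <- ev$n_rejected
  list(networks = networks, tables = tables, fits = fits,
       summaries = summaries, vif = vifs, log = log)
}

# Cumulative parental-association covariate via SRI-matrix lookups on a
# prebuilt (unfiltered) cumulative network; absent birds contribute 0.
# Returns NA where the focal (and, in peer mode, the partner) has no
# tagged parent.
parental_assoc_from_net <- function(net, focal_ids, partner_ids, mode,
                                    birds) {
  look <- function(a, b) {
    ia <- match(a, net$birds)
    ib <- match(b, net$birds)
    out <- rep(0, length(a))
    ok <- !is.na(ia) & !is.na(ib)
    out[ok] <- net$sri[cbind(ia[ok], ib[ok])]
    out
  }
  bi <- match(focal_ids, birds$tag_id)
  mo <- birds$mother_id[bi]
  fa <- birds$father_id[bi]
  if (mode == "adult") {
    out <- ifelse(is.na(mo), 0, look(partner_ids, mo)) +
      ifelse(is.na(fa), 0, look(partner_ids, fa))
    out[is.na(mo) & is.na(fa)] <- NA_real_
    return(out)
  }
  pj <- match(partner_ids, birds$tag_id)
  mo2 <- birds$mother_id[pj]
  fa2 <- birds$father_id[pj]
  out <- rep(0, length(focal_ids))
  for (p1 in list(mo, fa)) {
    for (p2 in list(mo2, fa2)) {
      ok <- !is.na(p1) & !is.na(p2)
      if (any(ok)) out[ok] <- out[ok] + look(p1[ok], p2[ok])
    }
  }
  out[(is.na(mo) & is.na(fa)) | (is.na(mo2) & is.na(fa2))] <- NA_real_
  out
}

# VIF on the main-effect columns of a spec's design (interactions
# excluded, intercept dropped).
vif_for_spec <- function(dyad_table, spec) {
  main_spec <- zib_model_spec(spec$fixed_terms, interactions = list(),
                              chains = spec$chains,
                              iterations = spec$iterations,
                              warmup = spec$warmup, seed = spec$seed)
  X <- build_design(dyad_table, main_spec)$X
  X <- X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
  if (ncol(X) < 2) return(NULL)
  vif(X)
}

#' Run the seasonal analyses (assortativity; stability Models 5a-c)
#'
#' Builds one pooled network per season — the later seasons pool their
#' three 48-h deployments; summer uses its final three weekly
#' deployments for consistency — applying the inclusion filter to the
#' pooled group counts. Then, per season, computes assortativity by age
#' class with its node-permutation p-value, and for each consecutive
#' season pair fits the stability model: current SRI regressed on
#' previous-season SRI x age class plus space-use overlap, on the
#' both-directions dyad table restricted to birds observed in both
#' seasons.
#'
#' @inheritParams run_ontogeny_analysis
#' @return List with `networks` (per season), `assortativity` (data
#'   frame `season`, `r_assort`, `p_assort`, `n_perm`, `n_first_year`,
#'   `n_adult`), `tables`, `fits`, `summaries` per transition, and
#'   `log`.
#' @export
run_seasonal_analysis <- function(detections, birds, schedule,
                                  config = study_config(),
                                  fit_models = TRUE) {
  ev <- detect_gathering_events(detections, schedule, config$events)
  feeders <- sort(unique(schedule$feeder_id))
  seasons <- c("summer", "autumn", "winter", "spring")
  present <- intersect(seasons, unique(schedule$season))
  networks <- list()
  season_windows <- list()
  for (s in present) {
    sch <- schedule[schedule$season == s, ]
    wins <- unique(sch$window_label[order(sch$start_s)])
    if (s == "summer") wins <- tail(wins, 3)
    season_windows[[s]] <- wins
    gbis <- window_memberships(ev, wins)
    gbis <- gbis[vapply(gbis, nrow, 0L) > 0]
    if (length(gbis) == 0) next
    pooled <- pool_deployments(gbis)
    networks[[s]] <- suppressWarnings(
      build_network(pooled, s, config$min_groups))
  }
  perm_seed <- stage_seed(config$seed, "permutation")
  assort_rows <- list()
  for (s in names(networks)) {
    net <- networks[[s]]
    if (length(net$birds) < 2) next
    labels <- setNames(birds$age_class[match(net$birds, birds$tag_id)],
                       net$birds)
    if (length(unique(labels)) < 2) next
    res <- node_permutation_pvalue(net, labels, n_perm = config$n_perm,
                                   seed = perm_seed + match(s, seasons))
    assort_rows[[s]] <- data.frame(
      season = s, r_assort = res$r_assort, p_assort = res$p_assort,
      n_perm = res$n_perm,
      n_first_year = sum(labels == "first_year"),
      n_adult = sum(labels == "adult"))
  }
  assortativity <- if (length(assort_rows)) do.call(rbind, assort_rows)
  else NULL
  tables <- fits <- summaries <- list()
  transitions <- list(autumn = c("summer", "autumn"),
                      winter = c("autumn", "winter"),
                      spring = c("winter", "spring"))
  for (tr in names(transitions)) {
    prev_s <- transitions[[tr]][1]
    cur_s <- transitions[[tr]][2]
    if (is.null(networks[[prev_s]]) || is.null(networks[[cur_s]])) next
    prev <- networks[[prev_s]]
    cur <- networks[[cur_s]]
    shared <- intersect(cur$birds, prev$birds)
    if (length(shared) < 2) {
      stop(sprintf("no dyads shared between %s and %s", prev_s, cur_s),
           call. = FALSE)
    }
    sub <- subset_network(cur, shared)
    wins <- season_windows[[cur_s]]
    sch <- schedule[schedule$window_label %in% wins, ]
    keep <- rep(FALSE, nrow(detections))
    for (r in seq_len(nrow(sch))) {
      keep <- keep | (detections$feeder_id == sch$feeder_id[r] &
                        detections$timestamp_s >= sch$start_s[r] &
                        detections$timestamp_s < sch$end_s[r])
    }
    prof <- feeder_profiles(detections[keep, ], shared, feeders)
    tb <- enumerate_dyads(sub, birds, "both_directions", "all",
                          profiles = prof,
                          overlap_method = config$overlap_method)
    tb$prev_season_sri <- prev$sri[cbind(match(tb$focal_id, prev$birds),
                                         match(tb$partner_id, prev$birds))]
    tables[[tr]] <- tb
    if (fit_models && nrow(tb) >= 20 &&
        length(unique(tb$focal_age_class)) >= 1) {
      spec <- config$models$model5
      if (length(unique(tb$focal_age_class)) < 2) {
        spec <- zib_model_spec(
          fixed_terms = c("prev_season_sri", "overlap"),
          chains = spec$chains, iterations = spec$iterations,
          warmup = spec$warmup, seed = spec$seed)
      }
      fits[[tr]] <- fit_zib_mm(tb, spec)
      summaries[[tr]] <- summarize_odds_ratios(fits[[tr]])
    }
  }
  list(networks = networks, assortativity = assortativity,
       tables = tables, fits = fits, summaries = summaries,
       log = list(n_rejected_reads = ev$n_rejected))
}

# Restrict a network to a subset of its birds (keeps SRI values; used to
# subset a seasonal network to birds also observed in the previous
# season).
subset_network <- function(net, keep) {
  ix <- match(keep, net$birds)
  out <- net
  out$birds <- keep
  out$group_count <- net$group_count[keep]
  for (f in c("sri", "x", "y_ab", "y_a", "y_b")) {
    out[[f]] <- net[[f]][ix, ix, drop = FALSE]
  }
  out
}

#' Write a dyad table as delimited text
#'
#' Column order follows the dyad-row contract; missing
#' `prev_season_sri` is written as an empty field.
#'
#' @param tb Dyad table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dyad_table <- function(tb, path) {
  cols <- intersect(c("focal_id", "partner_id", "window_label", "sri",
                      "relationship", "overlap", "focal_age_days",
                      "weight_diff_std", "age_diff_std",
                      "parental_assoc_cum", "prev_season_sri",
                      "focal_age_class"), names(tb))
  write.csv(tb[, cols], path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write model effect summaries as delimited text
#'
#' @param summaries Named list of data frames from
#'   [summarize_odds_ratios()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_effect_summaries <- function(summaries, path) {
  rows <- lapply(names(summaries), function(mn) {
    cbind(model = mn, summaries[[mn]])
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
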