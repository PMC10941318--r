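#' Per-feeder usage profile of one bird
#'
#' Counts how often a bird was registered on each feeder within a time
#' window, the proxy for time spent in each feeder area that underlies
#' the space-use-overlap covariate.
#'
#' @param detections Detection data frame (`tag_id`, `feeder_id`,
#'   `timestamp_s`), already restricted to the window of interest (or
#'   pass `window` and `schedule` to restrict here).
#' @param bird Tag ID.
#' @param feeders Character vector of feeder IDs fixing the order and
#'   length of the profile.
#' @param window,schedule Optional window label and schedule table used
#'   to subset `detections` to that window's deployment intervals.
#' @return Named integer vector over `feeders`, summing to the bird's
#'   total reads in the window; all zeros (with a warning) for a bird
#'   absent from the window.
#' @export
feeder_usage_profile <- function(detections, bird, feeders,
                                 window = NULL, schedule = NULL) {
  det <- detections
  if (!is.null(window)) {
    stopifnot(!is.null(schedule))
    sch <- schedule[schedule$window_label == window, ]
    keep <- rep(FALSE, nrow(det))
    for (r in seq_len(nrow(sch))) {
      keep <- keep | (det$feeder_id == sch$feeder_id[r] &
                        det$timestamp_s >= sch$start_s[r] &
                        det$timestamp_s < sch$end_s[r])
    }
    det <- det[keep, ]
  }
  det <- det[det$tag_id == bird, ]
  prof <- setNames(integer(length(feeders)), feeders)
  if (nrow(det) == 0) {
    warning(sprintf("bird '%s' has no reads in this window", bird),
            call. = FALSE)
    return(prof)
  }
  tab <- table(factor(det$feeder_id, levels = feeders))
  prof[] <- as.integer(tab)
  prof
}

# All birds at once: birds x feeders read-count matrix.
feeder_profiles <- function(detections, birds, feeders) {
  tab <- table(factor(detections$tag_id, levels = birds),
               factor(detections$feeder_id, levels = feeders))
  m <- matrix(as.integer(tab), length(birds), length(feeders),
              dimnames = list(birds, feeders))
  m
}

#' Space-use overlap of a dyad
#'
#' Default (`"proportion"`): the fraction of the focal bird's reads made
#' at feeders where the partner was registered at least once — the
#' overlap of time spent in feeder areas as a proportion of the focal
#' individual's overall time observed (0 = no overlap, 1 = full
#' overlap). Asymmetric in general. The symmetric alternative
#' (`"min_share"`) is `sum_f min(p_focal_f, p_partner_f)` of the two
#' normalised profiles.
#'
#' @param focal_profile,partner_profile Per-feeder read counts (same
#'   feeder order).
#' @param method `"proportion"` (default) or `"min_share"`.
#' @return Overlap in `[0, 1]`; a focal bird with zero total reads is an
#'   error (it should have been filtered upstream).
#' @export
space_overlap <- function(focal_profile, partner_profile,
                          method = c("proportion", "min_share")) {
  method <- match.arg(method)
  tot <- sum(focal_profile)
  if (tot == 0) stop("focal bird has no reads", call. = FALSE)
  if (method == "proportion") {
    sum(focal_profile[partner_profile > 0]) / tot
  } else {
    p <- focal_profile / tot
    q <- partner_profile / sum(partner_profile)
    sum(pmin(p, q))
  }
}

#' Relationship class of a dyad
#'
#' Classifies the partner from the focal bird's viewpoint: `parents` if
#' the partner is the focal's recorded mother or father (or the focal is
#' the partner's), `siblings` if the two share both recorded parents,
#' `peers` for any other first-year pair, `other_adults` otherwise. The
#' four classes are mutually exclusive and exhaustive.
#'
#' @param focal,partner Tag IDs, both present in `birds`.
#' @param birds Population table with pedigree columns.
#' @return One of `"parents"`, `"siblings"`, `"peers"`, `"other_adults"`.
#' @export
relationship_type <- function(focal, partner, birds) {
  for (id in c(focal, partner)) {
    if (!id %in% birds$tag_id) {
      stop(sprintf("bird '%s' not in metadata table", id), call. = FALSE)
    }
  }
  i <- match(focal, birds$tag_id)
  j <- match(partner, birds$tag_id)
  pa_i <- c(birds$mother_id[i], birds$father_id[i])
  pa_j <- c(birds$mother_id[j], birds$father_id[j])
  if (partner %in% pa_i[!is.na(pa_i)] || focal %in% pa_j[!is.na(pa_j)]) {
    return("parents")
  }
  if (!anyNA(c(pa_i, pa_j)) && all(pa_i == pa_j)) return("siblings")
  if (birds$age_class[i] == "first_year" &&
      birds$age_class[j] == "first_year") {
    return("peers")
  }
  "other_adults"
}

# SRI between two birds on an (unfiltered) pooled membership table,
# returning 0 when either bird was never observed there.
sri_or_zero <- function(membership, a, b) {
  if (is.na(a) || is.na(b)) return(0)
  if (!a %in% colnames(membership) || !b %in% colnames(membership)) return(0)
  cn <- sri_counts(membership, a, b)
  if (sum(cn) == 0) return(0)
  simple_ratio_index(cn["x"], cn["y_ab"], cn["y_a"], cn["y_b"])
}

#' Cumulative association with or between parents
#'
#' Computes the parental-network covariate on data pooled from the first
#' week up to the current one (week `t` uses weeks `1..t`). In `"adult"`
#' mode it is the summed association strength between the counterpart
#' adult and the juvenile's mother and father; in `"peer"` mode, the sum
#' over all (up to four) pairs of the two juveniles' parents. SRI terms
#' involving an untagged or never-observed parent contribute 0; the
#' pooled table is used unfiltered because this is a covariate, not a
#' response.
#'
#' @param memberships List of weekly membership tables for weeks `1..t`.
#' @param juvenile Focal juvenile tag ID.
#' @param counterpart Partner tag ID (an adult in `"adult"` mode, a peer
#'   in `"peer"` mode).
#' @param mode `"adult"` or `"peer"`.
#' @param birds Population table (pedigree source).
#' @return Nonnegative real; `NA` (row to be excluded) when the focal
#'   juvenile — and in `"peer"` mode also the counterpart — has no tagged
#'   parent at all.
#' @export
cumulative_parental_association <- function(memberships, juvenile,
                                            counterpart,
                                            mode = c("adult", "peer"),
                                            birds) {
  mode <- match.arg(mode)
  stopifnot(length(memberships) >= 1)
  pooled <- if (length(memberships) == 1) memberships[[1]] else
    pool_deployments(memberships)
  i <- match(juvenile, birds$tag_id)
  pa <- c(birds$mother_id[i], birds$father_id[i])
  pa <- pa[!is.na(pa)]
  if (length(pa) == 0) return(NA_real_)
  if (mode == "adult") {
    sum(vapply(pa, function(p) sri_or_zero(pooled, counterpart, p), 0))
  } else {
    j <- match(counterpart, birds$tag_id)
    pb <- c(birds$mother_id[j], birds$father_id[j])
    pb <- pb[!is.na(pb)]
    if (length(pb) == 0) return(NA_real_)
    sum(vapply(pa, function(p1) {
      sum(vapply(pb, function(p2) sri_or_zero(pooled, p1, p2), 0))
    }, 0))
  }
}

#' Center or z-score a covariate, keeping the transform parameters
#'
#' @param values Numeric vector.
#' @param mode `"center"` subtracts the mean; `"zscore"` also divides by
#'   the sample standard deviation.
#' @return Transformed vector with attributes `center` and `scale` so the
#'   transform can be reported and inverted. Zero variance under
#'   `"zscore"` is an error.
#' @export
center_and_standardize <- function(values, mode = c("center", "zscore")) {
  mode <- match.arg(mode)
  ctr <- mean(values)
  scl <- 1
  if (mode == "zscore") {
    if (length(unique(values)) < 2) {
      stop("zscore needs at least 2 distinct values", call. = FALSE)
    }
    scl <- sd(values)
    if (scl == 0) stop("zero variance under zscore", call. = FALSE)
  }
  out <- (values - ctr) / scl
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

#' Enumerate dyad rows of an association network
#'
#' Builds the directed focal-partner analysis table for one network.
#' `"both_directions"` yields every ordered pair of retained birds —
#' exactly `n(n-1)` rows — with each bird once the focal and once the
#' non-focal member of each dyad; `"juvenile_focal"` yields only rows
#' whose focal bird is a first-year. Symmetric covariates (SRI, weight
#' and hatch-date differences) are identical in the two directions;
#' focal-specific ones (age, space-use overlap) are recomputed per
#' direction. Weight/age differences are absolute values (raw here;
#' standardisation happens at model-table assembly).
#'
#' @param net An `assoc_network`.
#' @param birds Population table (ages, pedigree).
#' @param mode `"both_directions"` or `"juvenile_focal"`.
#' @param partners Restrict partners: `"all"`, `"peers"` (non-sibling
#'   first-year pairs) or `"nonparent_adults"` (adult partners excluding
#'   the focal's parents).
#' @param profiles Optional birds x feeders read-count matrix for the
#'   window (required for the `overlap` column).
#' @param window_day Optional study-clock day of the window's start, used
#'   for `focal_age_days` (days since fledging).
#' @param overlap_method Passed to [space_overlap()].
#' @return Data frame with one row per directed dyad: `focal_id`,
#'   `partner_id`, `window_label`, `sri`, `relationship`, `overlap`,
#'   `focal_age_days`, `weight_diff`, `age_diff`, `focal_age_class`.
#' @export
enumerate_dyads <- function(net, birds,
                            mode = c("both_directions", "juvenile_focal"),
                            partners = c("all", "peers",
                                         "nonparent_adults"),
                            profiles = NULL, window_day = NULL,
                            overlap_method = "proportion") {
  mode <- match.arg(mode)
  partners <- match.arg(partners)
  stopifnot(inherits(net, "assoc_network"))
  ids <- net$birds
  missing_meta <- setdiff(ids, birds$tag_id)
  if (length(missing_meta) > 0) {
    stop("network birds missing from metadata: ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  }
  bi <- birds[match(ids, birds$tag_id), ]
  rel <- relationship_matrix(bi)
  n <- length(ids)
  pair <- expand.grid(fi = seq_len(n), pi = seq_len(n))
  pair <- pair[pair$fi != pair$pi, ]
  if (mode == "juvenile_focal") {
    pair <- pair[bi$age_class[pair$fi] == "first_year", ]
  }
  rel_vec <- rel[cbind(pair$fi, pair$pi)]
  if (partners == "peers") {
    pair <- pair[rel_vec == "peers", ]
  } else if (partners == "nonparent_adults") {
    pair <- pair[bi$age_class[pair$pi] == "adult" &
                   rel_vec != "parents", ]
  }
  rel_vec <- rel[cbind(pair$fi, pair$pi)]
  if (nrow(pair) == 0) {
    return(data.frame(focal_id = character(), partner_id = character(),
                      window_label = character(), sri = numeric(),
                      relationship = character(), overlap = numeric(),
                      focal_age_days = numeric(), weight_diff = numeric(),
                      age_diff = numeric(), focal_age_class = character(),
                      stringsAsFactors = FALSE))
  }
  sri <- net$sri[cbind(pair$fi, pair$pi)]
  overlap <- rep(NA_real_, nrow(pair))
  if (!is.null(profiles)) {
    missing_prof <- setdiff(ids, rownames(profiles))
    if (length(missing_prof) > 0) {
      stop("profiles missing for: ", paste(missing_prof, collapse = ", "),
           call. = FALSE)
    }
    pr <- profiles[ids, , drop = FALSE]
    overlap <- vapply(seq_len(nrow(pair)), function(r) {
      space_overlap(pr[pair$fi[r], ], pr[pair$pi[r], ],
                    method = overlap_method)
    }, 0)
  }
  age_days <- if (!is.null(window_day)) {
    window_day - bi$fledge_date[pair$fi]
  } else rep(NA_real_, nrow(pair))
  data.frame(
    focal_id = ids[pair$fi],
    partner_id = ids[pair$pi],
    window_label = net$window_label,
    sri = sri,
    relationship = rel_vec,
    overlap = overlap,
    focal_age_days = as.numeric(age_days),
    weight_diff = abs(bi$fledge_weight_g[pair$fi] -
                        bi$fledge_weight_g[pair$pi]),
    age_diff = abs(bi$hatch_date[pair$fi] - bi$hatch_date[pair$pi]),
    focal_age_class = bi$age_class[pair$fi],
    stringsAsFactors = FALSE)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)`, with `R^2_j` from the least-squares
#' regression of predictor `j` on all other predictors (main effects
#' only; interaction columns are screened before they are formed).
#' Exactly collinear columns are reported as `Inf`.
#'
#' @param X Numeric design matrix of main-effect predictors (no
#'   intercept column), at least two columns.
#' @return Named vector of VIFs, one per column.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need at least 2 predictors", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  vapply(seq_len(ncol(X)), function(j) {
    fit <- lm(X[, j] ~ X[, -j, drop = FALSE])
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 > 1 - 1e-10) Inf else 1 / (1 - r2)
  }, 0) |> setNames(colnames(X))
}
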