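# Small in-code fixtures and independent oracles shared across tests.

# Membership matrix from a list of groups (character vectors of tags).
make_membership <- function(groups, birds = NULL, events = NULL) {
  tags <- if (is.null(birds)) sort(unique(unlist(groups))) else birds
  m <- matrix(0L, length(groups), length(tags),
              dimnames = list(sprintf("G%03d", seq_along(groups)), tags))
  for (i in seq_along(groups)) m[i, groups[[i]]] <- 1L
  if (!is.null(events)) {
    events$event_id <- rownames(m)
    attr(m, "events") <- events
  }
  m
}

# Random membership table: each bird joins each group independently.
rand_membership <- function(n_groups, n_birds, p = 0.4) {
  tags <- sprintf("B%02d", seq_len(n_birds))
  m <- matrix(rbinom(n_groups * n_birds, 1, p), n_groups, n_birds,
              dimnames = list(sprintf("G%03d", seq_len(n_groups)), tags))
  # no empty groups (regenerate empty rows deterministically)
  for (i in which(rowSums(m) == 0)) m[i, sample(n_birds, 1)] <- 1L
  m
}

# Independent SRI oracle: naive per-group loop, including the
# overlapping-group y_AB rule when event metadata is present.
brute_sri_counts <- function(membership, a, b) {
  ev <- attr(membership, "events")
  n_g <- nrow(membership)
  overlaps_with_other <- function(g, bird) {
    if (is.null(ev)) return(FALSE)
    for (h in seq_len(n_g)) {
      if (h == g) next
      if (ev$feeder_id[h] != ev$feeder_id[g]) next
      if (ev$start_s[h] > ev$end_s[g] || ev$end_s[h] < ev$start_s[g]) next
      if (membership[h, bird] > 0) return(TRUE)
    }
    FALSE
  }
  x <- y_ab <- y_a <- y_b <- 0L
  for (g in seq_len(n_g)) {
    ina <- membership[g, a] > 0
    inb <- membership[g, b] > 0
    if (ina && inb) {
      x <- x + 1L
    } else if (ina) {
      if (overlaps_with_other(g, b)) y_ab <- y_ab + 1L else y_a <- y_a + 1L
    } else if (inb) {
      if (overlaps_with_other(g, a)) y_ab <- y_ab + 1L else y_b <- y_b + 1L
    }
  }
  c(x = x, y_ab = y_ab, y_a = y_a, y_b = y_b)
}

# Independent weighted-assortativity oracle: direct double sum over the
# weight matrix (no mixing-matrix construction).
brute_assortativity <- function(w, labels) {
  nodes <- rownames(w)
  lab <- labels[nodes]
  classes <- unique(lab)
  tot <- 0
  within <- 0
  marg <- setNames(numeric(length(classes)), classes)
  n <- nrow(w)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      tot <- tot + w[i, j]
      if (lab[i] == lab[j]) within <- within + w[i, j]
      marg[lab[i]] <- marg[lab[i]] + w[i, j] / 2
      marg[lab[j]] <- marg[lab[j]] + w[i, j] / 2
    }
  }
  e_within <- within / tot
  ab <- sum((marg / tot)^2)
  (e_within - ab) / (1 - ab)
}

# A small pedigree: 2 boxes x 2 nestlings + 2 adult pairs + 1 extra adult.
toy_birds <- function() {
  data.frame(
    tag_id = c("AF1", "AM1", "AF2", "AM2", "AX",
               "J1", "J2", "J3", "J4"),
    age_class = c(rep("adult", 5), rep("first_year", 4)),
    hatch_date = c(rep(NA, 5), -20, -20, -15, -15),
    fledge_date = c(rep(NA, 5), 2, 2, 7, 7),
    fledge_weight_g = c(rep(NA, 5), 17.5, 18.2, 19.1, 16.9),
    natal_box = c(rep(NA, 5), "B1", "B1", "B2", "B2"),
    mother_id = c(rep(NA, 5), "AF1", "AF1", "AF2", "AF2"),
    father_id = c(rep(NA, 5), "AM1", "AM1", "AM2", "AM2"),
    stringsAsFactors = FALSE)
}

# Desk-scale world used by several suites; named arguments override the
# desk defaults.
desk_config <- function(seed, ...) {
  args <- list(n_nest_boxes = 6, mean_clutch_size = 6.5,
               n_weekly_deployments = 3, deployment_duration_h = 12,
               event_rate = 5, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(world_config, args)
}

# A weight matrix with two perfectly-assorted blocks.
two_block_network <- function(n_per = 5, between = 0) {
  n <- 2 * n_per
  w <- matrix(0, n, n)
  w[seq_len(n_per), seq_len(n_per)] <- 0.5
  w[n_per + seq_len(n_per), n_per + seq_len(n_per)] <- 0.5
  if (between > 0) {
    w[seq_len(n_per), n_per + seq_len(n_per)] <- between
    w[n_per + seq_len(n_per), seq_len(n_per)] <- between
  }
  diag(w) <- 0
  rownames(w) <- colnames(w) <- sprintf("N%02d", seq_len(n))
  w
}

two_block_labels <- function(n_per = 5) {
  setNames(rep(c("first_year", "adult"), each = n_per),
           sprintf("N%02d", seq_len(2 * n_per)))
}
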