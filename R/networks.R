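#' Simple ratio index from its four counts
#'
#' `SRI = x / (x + y_AB + y_A + y_B)`: the proportion of sampling groups
#' in which the dyad was seen together out of all groups in which either
#' member was seen. Ranges from 0 (never observed in the same group) to 1
#' (always observed in the same group).
#'
#' @param x Groups containing both birds.
#' @param y_ab Occasions where both were observed but in different,
#'   time-overlapping groups.
#' @param y_a,y_b Groups containing only the one bird.
#' @return SRI in `[0, 1]`. All-zero counts are an error: such dyads are
#'   unobservable and should have been removed by the inclusion filter.
#' @export
simple_ratio_index <- function(x, y_ab, y_a, y_b) {
  counts <- c(x, y_ab, y_a, y_b)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("SRI counts must be nonnegative integers", call. = FALSE)
  }
  denom <- x + y_ab + y_a + y_b
  if (any(denom == 0)) {
    stop("SRI undefined for a dyad with no observations", call. = FALSE)
  }
  x / denom
}

# Index (per event) of which other birds were present in a different,
# time-overlapping group at the same feeder.  Returns an events x birds
# logical matrix; all FALSE when the membership table carries no event
# metadata (then y_AB is identically 0).
overlap_presence <- function(membership) {
  ev <- attr(membership, "events")
  ne <- nrow(membership)
  N <- matrix(FALSE, ne, ncol(membership),
              dimnames = dimnames(membership))
  if (is.null(ev) || ne < 2 ||
      !all(c("feeder_id", "start_s", "end_s") %in% names(ev))) {
    return(N)
  }
  ev <- ev[match(rownames(membership), ev$event_id), ]
  for (f in unique(ev$feeder_id)) {
    ix <- which(ev$feeder_id == f)
    if (length(ix) < 2) next
    ix <- ix[order(ev$start_s[ix])]
    for (i in seq_along(ix)[-1]) {
      g <- ix[i]
      for (j in rev(seq_len(i - 1))) {
        h <- ix[j]
        if (ev$end_s[h] < ev$start_s[g]) break
        N[g, membership[h, ] > 0] <- TRUE
        N[h, membership[g, ] > 0] <- TRUE
      }
    }
  }
  N
}

#' Simple-ratio-index counts for one dyad
#'
#' Counts, over the groups of a membership table: `x` groups containing
#' both birds; `y_a` / `y_b` groups containing only the one; and `y_ab`
#' group observations of one bird while the other was present in a
#' different group whose time span overlapped at the same feeder (zero
#' when the table carries no event metadata, or when no groups overlap in
#' time — the event detector partitions reads, so overlap is rare).
#'
#' @param membership Group-by-individual matrix from
#'   [group_by_individual()].
#' @param a,b Tag IDs (distinct, both present as columns).
#' @return Named integer vector `c(x, y_ab, y_a, y_b)`.
#' @export
sri_counts <- function(membership, a, b) {
  if (a == b) stop("`a` and `b` must differ", call. = FALSE)
  for (id in c(a, b)) {
    if (!id %in% colnames(membership)) {
      stop(sprintf("bird '%s' not present in membership table", id),
           call. = FALSE)
    }
  }
  ca <- membership[, a] > 0
  cb <- membership[, b] > 0
  N <- overlap_presence(membership)
  na_b <- N[, b]
  na_a <- N[, a]
  c(x = sum(ca & cb),
    y_ab = sum(ca & !cb & na_b) + sum(cb & !ca & na_a),
    y_a = sum(ca & !cb & !na_b),
    y_b = sum(cb & !ca & !na_a))
}

#' Inclusion filter: drop birds seen in too few distinct groups
#'
#' Birds detected in fewer than `min_groups` distinct groups are removed
#' from the membership table; groups left with no members are then
#' dropped. The filter is applied once (survivors are not re-screened
#' after groups empty out).
#'
#' @param membership Group-by-individual matrix.
#' @param min_groups Minimum distinct-group count (default 5).
#' @return Filtered membership matrix with its `"events"` attribute
#'   subset to the surviving groups.
#' @export
apply_min_group_filter <- function(membership, min_groups = 5) {
  keep_birds <- colSums(membership) >= min_groups
  m <- membership[, keep_birds, drop = FALSE]
  keep_groups <- rowSums(m) > 0
  ev <- attr(membership, "events")
  m <- m[keep_groups, , drop = FALSE]
  if (!is.null(ev)) {
    attr(m, "events") <- ev[match(rownames(m), ev$event_id), , drop = FALSE]
  }
  m
}

#' Build a simple-ratio-index association network
#'
#' Applies the minimum-group inclusion filter, then computes all-pairs
#' SRI among the retained birds. Every retained bird has at least
#' `min_groups` groups, so no retained dyad has an undefined (all-zero)
#' index.
#'
#' @param membership Group-by-individual matrix for one time window.
#' @param window_label Label for the window (e.g. `"week-07"`,
#'   `"autumn"`).
#' @param min_groups Inclusion threshold (default 5 distinct groups).
#' @return Object of class `assoc_network`: list with `window_label`,
#'   `birds`, `group_count`, `n_groups`, and symmetric matrices `sri`,
#'   `x`, `y_ab`, `y_a`, `y_b`.
#' @export
build_network <- function(membership, window_label, min_groups = 5) {
  m <- apply_min_group_filter(membership, min_groups)
  birds <- colnames(m)
  n <- length(birds)
  if (n < 2) {
    warning("fewer than 2 birds retained; network has no edges",
            call. = FALSE)
    empty <- matrix(numeric(0), n, n, dimnames = list(birds, birds))
    return(structure(list(window_label = window_label, birds = birds,
                          group_count = colSums(m), n_groups = nrow(m),
                          sri = empty, x = empty, y_ab = empty,
                          y_a = empty, y_b = empty),
                     class = "assoc_network"))
  }
  M <- m
  storage.mode(M) <- "double"
  N <- overlap_presence(m)
  x <- crossprod(M)
  # W[g, b] = 1 iff b absent from group g but present in an overlapping
  # group; (t(M) W)[a, b] then counts a's groups contributing to y_AB.
  W <- (1 - M) * N
  U <- (1 - M) * (1 - N)
  yab_side <- crossprod(M, W)
  y_ab <- yab_side + t(yab_side)
  y_a <- crossprod(M, U)
  y_b <- t(y_a)
  denom <- x + y_ab + y_a + y_b
  sri <- x / denom
  diag(sri) <- 0
  diag(x) <- diag(y_ab) <- diag(y_a) <- diag(y_b) <- 0
  structure(list(window_label = window_label, birds = birds,
                 group_count = colSums(m), n_groups = nrow(m),
                 sri = sri, x = x, y_ab = y_ab, y_a = y_a, y_b = y_b),
            class = "assoc_network")
}

#' @export
print.assoc_network <- function(x, ...) {
  cat(sprintf("<assoc_network '%s': %d birds, %d groups>\n",
              x$window_label, length(x$birds), x$n_groups))
  if (length(x$birds) >= 2) {
    w <- x$sri[upper.tri(x$sri)]
    cat(sprintf("  nonzero edges: %d/%d; mean SRI %.4f\n",
                sum(w > 0), length(w), mean(w)))
  }
  invisible(x)
}

#' Pool membership tables from several deployments
#'
#' Row-concatenates the group-by-individual tables of several 48-h
#' deployments into one table for a season, aligning birds on the union
#' of tag IDs. Per-bird group counts of the pooled table are the sums of
#' the per-deployment counts, so the inclusion filter applied afterwards
#' thresholds groups across all pooled deployments.
#'
#' @param tables List of membership matrices.
#' @return Pooled membership matrix; duplicated event IDs are an error.
#' @export
pool_deployments <- function(tables) {
  stopifnot(length(tables) >= 1)
  ids <- unlist(lapply(tables, rownames))
  if (anyDuplicated(ids)) {
    stop("duplicated event IDs across pooled deployments", call. = FALSE)
  }
  birds <- sort(unique(unlist(lapply(tables, colnames))))
  pooled <- matrix(0L, length(ids), length(birds),
                   dimnames = list(ids, birds))
  at <- 0
  evs <- list()
  for (tb in tables) {
    rows <- at + seq_len(nrow(tb))
    pooled[rows, colnames(tb)] <- tb
    at <- at + nrow(tb)
    ev <- attr(tb, "events")
    if (!is.null(ev)) evs[[length(evs) + 1]] <- ev
  }
  if (length(evs) == length(tables)) {
    common <- Reduce(intersect, lapply(evs, names))
    attr(pooled, "events") <- do.call(
      rbind, lapply(evs, function(e) e[, common, drop = FALSE]))
  }
  pooled
}

#' Edge list of an association network
#'
#' @param net An `assoc_network`.
#' @return Data frame `window`, `bird_a`, `bird_b`, `sri`, `x`, `y_ab`,
#'   `y_a`, `y_b`, one row per unordered dyad.
#' @export
as_edge_list <- function(net) {
  stopifnot(inherits(net, "assoc_network"))
  n <- length(net$birds)
  if (n < 2) {
    return(data.frame(window = character(), bird_a = character(),
                      bird_b = character(), sri = numeric(), x = numeric(),
                      y_ab = numeric(), y_a = numeric(), y_b = numeric()))
  }
  ut <- which(upper.tri(net$sri), arr.ind = TRUE)
  data.frame(window = net$window_label,
             bird_a = net$birds[ut[, 1]],
             bird_b = net$birds[ut[, 2]],
             sri = net$sri[ut],
             x = net$x[ut],
             y_ab = net$y_ab[ut],
             y_a = net$y_a[ut],
             y_b = net$y_b[ut])
}

#' Export an association network as GraphML
#'
#' @param net An `assoc_network`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "assoc_network"))
  g <- igraph::graph_from_adjacency_matrix(net$sri, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$group_count <- as.numeric(net$group_count[net$birds])
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
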