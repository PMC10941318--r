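feeders6 <- sprintf("F%d", 1:6)

test_that("feeder usage profiles count reads per feeder", {
  det <- data.frame(
    tag_id = c(rep("B1", 100), rep("B2", 10)),
    feeder_id = c(rep("F1", 60), rep("F2", 40), rep("F3", 10)),
    timestamp_s = seq_len(110))
  p <- feeder_usage_profile(det, "B1", feeders6)
  expect_equal(unname(p), c(60, 40, 0, 0, 0, 0))
  expect_equal(sum(p), 100)
  # order independence
  shuf <- det[sample(nrow(det)), ]
  expect_equal(feeder_usage_profile(shuf, "B1", feeders6), p)
  expect_warning(p0 <- feeder_usage_profile(det, "B9", feeders6),
                 "no reads")
  expect_equal(sum(p0), 0)
})

test_that("space overlap follows the focal-proportion reading", {
  focal <- c(F1 = 60, F2 = 40, F3 = 0, F4 = 0, F5 = 0, F6 = 0)
  expect_equal(space_overlap(focal, c(0, 0, 5, 0, 0, 0)), 0)
  expect_equal(space_overlap(focal, c(1, 1, 1, 1, 1, 1)), 1)
  expect_equal(space_overlap(focal, c(9, 0, 0, 0, 0, 0)), 0.6)
  expect_error(space_overlap(focal * 0, focal), "no reads")
  # superset of the focal feeder set always gives 1
  expect_equal(space_overlap(focal, c(2, 3, 4, 0, 0, 0)), 1)
  # the min-share alternative is symmetric
  a <- c(10, 10, 0, 0, 0, 0); b <- c(5, 0, 5, 0, 0, 0)
  expect_equal(space_overlap(a, b, "min_share"),
               space_overlap(b, a, "min_share"))
})

test_that("relationship classes are exclusive and exhaustive", {
  birds <- toy_birds()
  expect_equal(relationship_type("J1", "AF1", birds), "parents")
  expect_equal(relationship_type("AF1", "J1", birds), "parents")
  expect_equal(relationship_type("J1", "J2", birds), "siblings")
  expect_equal(relationship_type("J1", "J3", birds), "peers")
  expect_equal(relationship_type("J1", "AX", birds), "other_adults")
  expect_equal(relationship_type("AF1", "AM1", birds), "other_adults")
  expect_error(relationship_type("J1", "ZZ", birds), "'ZZ'")
  # partition over every ordered pair
  ids <- birds$tag_id
  for (a in ids) for (b in ids) {
    if (a == b) next
    expect_true(relationship_type(a, b, birds) %in%
                  c("parents", "siblings", "peers", "other_adults"))
  }
})

test_that("cumulative parental association pools weeks 1..t", {
  birds <- toy_birds()
  wk <- function(groups, prefix) {
    m <- make_membership(groups, birds = birds$tag_id)
    rownames(m) <- paste0(prefix, seq_len(nrow(m)))
    m
  }
  # week 1: adult AX always with mother AF1; week 2: AX alone
  w1 <- wk(list(c("AX", "AF1"), c("AX", "AF1"), "J1"), "a")
  w2 <- wk(list("AX", "J1"), "b")
  expect_equal(
    cumulative_parental_association(list(w1), "J1", "AX", "adult", birds),
    1)  # SRI(AX, AF1) = 1, father unseen contributes 0
  v2 <- cumulative_parental_association(list(w1, w2), "J1", "AX", "adult",
                                        birds)
  # pooled weeks 1..2: AX with AF1 in 2 of 3 of AX's groups, AF1 in none
  # alone; brute-force SRI on the pooled table is the oracle
  pooled <- pool_deployments(list(w1, w2))
  cn <- brute_sri_counts(pooled, "AX", "AF1")
  expect_equal(v2, unname(cn["x"] / sum(cn)))
  # adult never with either parent -> 0
  expect_equal(
    cumulative_parental_association(list(w2), "J1", "AX", "adult", birds),
    0)
  # peer mode sums over parent pairs
  w3 <- wk(list(c("AF1", "AF2"), c("AF1", "AF2")), "c")
  v3 <- cumulative_parental_association(list(w3), "J1", "J3", "peer",
                                        birds)
  expect_equal(v3, 1)  # SRI(AF1, AF2) = 1, other 3 pairs unseen
  # no tagged parents -> flagged NA
  loner <- rbind(birds, data.frame(
    tag_id = "J9", age_class = "first_year", hatch_date = -10,
    fledge_date = 12, fledge_weight_g = 18, natal_box = NA,
    mother_id = NA, father_id = NA))
  expect_true(is.na(cumulative_parental_association(
    list(w1), "J9", "AX", "adult", loner)))
})

test_that("centering and standardisation store invertible transforms", {
  x <- c(3, 5, 9, 11)
  ctr <- center_and_standardize(x, "center")
  expect_equal(sum(ctr), 0)
  zs <- center_and_standardize(x, "zscore")
  expect_equal(mean(zs), 0)
  expect_equal(sd(zs), 1)
  back <- as.numeric(zs) * attr(zs, "scale") + attr(zs, "center")
  expect_equal(back, x)
  expect_error(center_and_standardize(rep(2, 5), "zscore"), "distinct")
})

test_that("dyad enumeration yields n(n-1) directed rows", {
  # the printed seasonal group sizes imply the printed dyad counts
  sizes <- list(c(45, 30), c(25, 18), c(52, 53), c(27, 31))
  for (s in sizes) {
    n <- sum(s)
    ids <- sprintf("X%03d", seq_len(n))
    birds <- data.frame(
      tag_id = ids,
      age_class = rep(c("first_year", "adult"), s),
      hatch_date = c(rep(-20, s[1]), rep(NA, s[2])),
      fledge_date = c(rep(2, s[1]), rep(NA, s[2])),
      fledge_weight_g = c(rep(18, s[1]), rep(NA, s[2])),
      natal_box = NA, mother_id = NA, father_id = NA)
    m <- make_membership(rep(list(ids), 5), birds = ids)
    net <- build_network(m, "season", min_groups = 5)
    tb <- enumerate_dyads(net, birds, "both_directions", "all")
    expect_equal(nrow(tb), n * (n - 1))
  }
})

test_that("dyad enumeration handles focal modes and covariates", {
  birds <- toy_birds()
  ids <- c("J1", "J2", "AX")
  m <- make_membership(rep(list(ids), 5), birds = ids)
  net <- build_network(m, "week-01", min_groups = 5)
  both <- enumerate_dyads(net, birds, "both_directions", "all")
  expect_equal(nrow(both), 6)
  juv <- enumerate_dyads(net, birds, "juvenile_focal", "all")
  expect_equal(nrow(juv), 4)  # 2 juveniles x 2 partners
  expect_true(all(juv$focal_age_class == "first_year"))
  two <- enumerate_dyads(
    suppressWarnings(build_network(
      make_membership(rep(list(c("J1", "AX")), 5), birds = c("J1", "AX")),
      "w", 5)),
    birds, "both_directions", "all")
  expect_equal(nrow(two), 2)
  # focal-specific covariates recomputed per direction; symmetric copied
  prof <- matrix(c(10, 0, 0, 5, 5, 5), 3, 2, byrow = TRUE,
                 dimnames = list(ids, c("F1", "F2")))
  tb <- enumerate_dyads(net, birds, "both_directions", "all",
                        profiles = cbind(prof, F3 = 0, F4 = 0, F5 = 0,
                                         F6 = 0),
                        window_day = 7)
  r12 <- tb[tb$focal_id == "J1" & tb$partner_id == "J2", ]
  r21 <- tb[tb$focal_id == "J2" & tb$partner_id == "J1", ]
  expect_equal(r12$sri, r21$sri)
  expect_equal(r12$weight_diff, r21$weight_diff)
  expect_equal(r12$overlap, 0)    # J1 only at F1, J2 never there
  expect_equal(r21$overlap, 0)
  r13 <- tb[tb$focal_id == "J1" & tb$partner_id == "AX", ]
  r31 <- tb[tb$focal_id == "AX" & tb$partner_id == "J1", ]
  expect_equal(r13$overlap, 1)    # AX uses both of J1's feeders
  expect_equal(r31$overlap, 0.5)  # J1 covers only F1 of AX's two feeders
  expect_equal(r12$focal_age_days, 7 - 2)
  # peers / non-parent adult partner filters (J1 and J2 are siblings,
  # so no peer dyads exist in this network -> empty table)
  peers <- enumerate_dyads(net, birds, "both_directions", "peers")
  expect_equal(nrow(peers), 0)
  ids2 <- c("J1", "J3", "AX")
  net2 <- build_network(make_membership(rep(list(ids2), 5), birds = ids2),
                        "w2", 5)
  peers2 <- enumerate_dyads(net2, birds, "both_directions", "peers")
  expect_equal(nrow(peers2), 2)
  expect_true(all(peers2$relationship == "peers"))
  npa <- enumerate_dyads(net, birds, "juvenile_focal", "nonparent_adults")
  expect_true(all(npa$partner_id == "AX"))
  expect_error(enumerate_dyads(net, birds[birds$tag_id != "AX", ],
                               "both_directions", "all"),
               "missing from metadata")
})

test_that("VIF matches the least-squares oracle", {
  set.seed(61)
  X <- matrix(rnorm(300), 100, 3,
              dimnames = list(NULL, c("p1", "p2", "p3")))
  # orthogonalise -> all VIF ~ 1
  Xo <- qr.Q(qr(X))
  colnames(Xo) <- colnames(X)
  expect_equal(unname(vif(Xo)), rep(1, 3), tolerance = 1e-3)
  # correlated design: compare against car::vif and the normal equations
  X[, 2] <- X[, 1] + rnorm(100, 0, 0.5)
  v <- vif(X)
  lm_oracle <- function(j) {
    r2 <- summary(lm(X[, j] ~ X[, -j]))$r.squared
    1 / (1 - r2)
  }
  expect_equal(unname(v), vapply(1:3, lm_oracle, 0))
  if (requireNamespace("car", quietly = TRUE)) {
    df <- as.data.frame(X)
    df$y <- rnorm(100)
    expect_equal(unname(v),
                 unname(car::vif(lm(y ~ p1 + p2 + p3, data = df))),
                 tolerance = 1e-6)
  }
  # duplicated column -> infinite, flagged
  Xd <- cbind(X, p4 = X[, 1])
  expect_true(is.infinite(vif(Xd)["p4"]))
  expect_error(vif(X[, 1, drop = FALSE]), "2 predictors")
})
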