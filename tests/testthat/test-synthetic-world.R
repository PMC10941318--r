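test_that("population generation respects the pedigree invariants", {
  cfg <- world_config(seed = 3)
  birds <- generate_population(cfg)
  nest <- birds[birds$age_class == "first_year", ]
  adults <- birds[birds$age_class == "adult", ]
  expect_equal(nrow(adults), 2 * cfg$n_nest_boxes)
  # tagged-brood total close to its design mean (43 boxes x ~4.3/box)
  mu <- cfg$n_nest_boxes * cfg$mean_clutch_size * cfg$nestling_survival
  expect_gt(nrow(nest), mu - 4 * sqrt(mu))
  expect_lt(nrow(nest), mu + 4 * sqrt(mu))
  expect_equal(length(unique(nest$natal_box)), cfg$n_nest_boxes)
  # siblings share both parents; fledge follows hatch; weights positive
  by_box <- split(nest, nest$natal_box)
  for (b in by_box) {
    expect_equal(length(unique(b$mother_id)), 1)
    expect_equal(length(unique(b$father_id)), 1)
  }
  expect_true(all(nest$fledge_date > nest$hatch_date))
  expect_true(all(nest$fledge_weight_g > 0))
  expect_true(all(is.na(adults$mother_id)))
})

test_that("a single box yields one sibship sharing both parents", {
  birds <- generate_population(world_config(n_nest_boxes = 1,
                                            mean_clutch_size = 2,
                                            nestling_survival = 1,
                                            seed = 11))
  nest <- birds[birds$age_class == "first_year", ]
  expect_gte(nrow(nest), 1)
  expect_equal(length(unique(nest$mother_id)), 1)
  expect_equal(length(unique(nest$natal_box)), 1)
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- world_config(n_nest_boxes = 4, seed = 9)
  expect_identical(generate_population(cfg), generate_population(cfg))
  birds <- generate_population(cfg)
  s1 <- sample_social_structure(birds, cfg)
  s2 <- sample_social_structure(birds, cfg)
  expect_identical(s1, s2)
  d1 <- simulate_detections(birds, s1, cfg)
  d2 <- simulate_detections(birds, s2, cfg)
  expect_identical(d1$detections, d2$detections)
  expect_identical(d1$events, d2$events)
})

test_that("config invariants are enforced", {
  expect_error(world_config(mean_clutch_size = 0), "clutch")
  expect_error(world_config(n_feeders = 0), "count")
  expect_error(world_config(preference_params = list(
    sibling = 0, parent = 1, peer = 1, other_adult = 1,
    familiarity_carryover = 0.5)), "multipliers")
  expect_error(world_config(preference_params = list(
    sibling = 1, parent = 1, peer = 1, other_adult = 1,
    familiarity_carryover = 2)), "carryover")
})

test_that("preference structure follows multiplier x home-range kernel", {
  birds <- toy_birds()
  cfg <- world_config(n_nest_boxes = 2, seed = 5,
                      preference_params = list(
                        sibling = 2, parent = 1, peer = 1,
                        other_adult = 1, familiarity_carryover = 1))
  soc <- sample_social_structure(birds, cfg)
  pref <- soc$preference$summer
  hr <- soc$home_range$summer
  expect_true(isSymmetric(pref))
  expect_true(all(diag(pref) == 0))
  expect_true(all(abs(rowSums(hr) - 1) < 1e-12))
  # sibling entry is exactly multiplier x Bhattacharyya kernel
  kern <- sum(sqrt(hr["J1", ] * hr["J2", ]))
  expect_equal(pref["J1", "J2"], 2 * kern)
  kern_ax <- sum(sqrt(hr["AX", ] * hr["AF1", ]))
  expect_equal(pref["AX", "AF1"], 1 * kern_ax)
  # full carryover: later seasons reuse the summer structure exactly
  expect_identical(soc$preference$winter, soc$preference$summer)
  expect_identical(soc$home_range$spring, soc$home_range$summer)
})

test_that("equal multipliers leave only the home-range kernel", {
  birds <- toy_birds()
  cfg <- world_config(n_nest_boxes = 2, seed = 5,
                      preference_params = list(
                        sibling = 1, parent = 1, peer = 1,
                        other_adult = 1, familiarity_carryover = 0.5))
  soc <- sample_social_structure(birds, cfg)
  pref <- soc$preference$summer
  hr <- soc$home_range$summer
  kern <- sqrt(hr) %*% t(sqrt(hr))
  diag(kern) <- 0
  expect_equal(pref, kern, ignore_attr = TRUE)
})

test_that("reads conserve the latent event mapping", {
  cfg <- desk_config(seed = 13, n_weekly_deployments = 2)
  birds <- generate_population(cfg)
  soc <- sample_social_structure(birds, cfg)
  sched <- build_schedule(cfg)
  sched <- sched[sched$season == "summer", ]
  sim <- simulate_detections(birds, soc, cfg, schedule = sched)
  # every read belongs to exactly one latent event; members are birds
  expect_true(all(sim$detections$event_id %in% sim$events$event_id))
  members <- unlist(strsplit(sim$events$member_tags, ";"))
  expect_true(all(members %in% birds$tag_id))
  # every attendee emits at least one read (member set == reader set,
  # checked for every event in one aggregated assertion)
  reads_by_event <- split(sim$detections$tag_id, sim$detections$event_id)
  ok <- vapply(seq_len(nrow(sim$events)), function(i) {
    setequal(unique(reads_by_event[[sim$events$event_id[i]]]),
             strsplit(sim$events$member_tags[i], ";")[[1]])
  }, NA)
  expect_true(all(ok))
  # reads stay inside their scheduled windows
  expect_true(all(sim$detections$timestamp_s >= min(sched$start_s)))
  expect_true(all(sim$detections$timestamp_s < max(sched$end_s)))
})

test_that("zero recruitment produces only singleton events", {
  cfg <- desk_config(seed = 17, n_weekly_deployments = 1,
                     recruitment_scale = 0)
  birds <- generate_population(cfg)
  soc <- sample_social_structure(birds, cfg)
  sched <- build_schedule(cfg)
  sched <- sched[sched$window_label == "week-01", ]
  sim <- simulate_detections(birds, soc, cfg, schedule = sched)
  expect_true(all(!grepl(";", sim$events$member_tags)))
})

test_that("empty population yields an empty stream, not an error", {
  cfg <- desk_config(seed = 1)
  birds <- generate_population(cfg)[0, ]
  soc <- list(preference = list(summer = matrix(0, 0, 0)))
  sim <- simulate_detections(birds, soc, cfg)
  expect_equal(nrow(sim$detections), 0)
  expect_equal(nrow(sim$events), 0)
})

test_that("latent co-membership SRI tracks the preference matrix", {
  # Monte-Carlo check against the generator's own event log
  # full default deployment design (14 weekly 48-h windows), reduced
  # population
  cfg <- world_config(n_nest_boxes = 12, seed = 19)
  birds <- generate_population(cfg)
  expect_gte(nrow(birds), 50)
  soc <- sample_social_structure(birds, cfg)
  sched <- build_schedule(cfg)
  sched <- sched[sched$season == "summer", ]
  sim <- simulate_detections(birds, soc, cfg, schedule = sched)
  gbi <- group_by_individual(sim$events, birds)
  net <- suppressWarnings(build_network(gbi, "latent", min_groups = 5))
  ids <- net$birds
  ut <- upper.tri(net$sri)
  rho <- cor(net$sri[ut], soc$preference$summer[ids, ids][ut],
             method = "spearman")
  expect_gt(rho, 0.5)
})

test_that("sibling co-membership responds monotonically to the multiplier", {
  co_memb <- function(sib) {
    cfg <- desk_config(seed = 23, n_weekly_deployments = 2,
                       preference_params = list(
                         sibling = sib, parent = 1, peer = 1,
                         other_adult = 1, familiarity_carryover = 0.75))
    birds <- generate_population(cfg)
    soc <- sample_social_structure(birds, cfg)
    sched <- build_schedule(cfg)
    sched <- sched[sched$season == "summer", ]
    sim <- simulate_detections(birds, soc, cfg, schedule = sched)
    gbi <- group_by_individual(sim$events, birds)
    rel <- flocknet:::relationship_matrix(birds)
    co <- crossprod(gbi)
    mean(co[!is.na(rel) & rel == "siblings"])
  }
  expect_gte(co_memb(3), co_memb(1))
})

test_that("world artefacts round-trip as plain text", {
  cfg <- desk_config(seed = 29, n_weekly_deployments = 1)
  birds <- generate_population(cfg)
  soc <- sample_social_structure(birds, cfg)
  sched <- build_schedule(cfg)
  sched <- sched[sched$window_label == "week-01", ]
  sim <- simulate_detections(birds, soc, cfg, schedule = sched)
  td <- withr::local_tempdir()
  write_detections(sim$detections, file.path(td, "d.csv"))
  write_birds(birds, file.path(td, "b.csv"))
  write_event_log(sim$events, file.path(td, "e.jsonl"))
  back <- load_detections(file.path(td, "d.csv"))
  expect_equal(nrow(back), nrow(sim$detections))
  expect_equal(back$tag_id, sim$detections$tag_id)
  expect_equal(back$timestamp_s, as.numeric(sim$detections$timestamp_s))
  lines <- readLines(file.path(td, "e.jsonl"))
  expect_equal(length(lines), nrow(sim$events))
  first <- jsonlite::fromJSON(lines[1])
  expect_equal(first$event_id, sim$events$event_id[1])
})
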