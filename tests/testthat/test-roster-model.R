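empty_tables <- function() {
  list(
    respondents = data.frame(
      ego_id = character(0), group = character(0), age_years = numeric(0),
      hiv_positive = logical(0), employed = logical(0),
      income_lt_20k = logical(0), stably_housed = logical(0),
      ever_jail = logical(0), insured = logical(0),
      in_relationship = logical(0), stringsAsFactors = FALSE),
    rosters = data.frame(
      ego_id = character(0), wave = integer(0), kind = character(0),
      nomination_id = character(0), position = integer(0),
      is_primary_partner = logical(0), alter_gender = character(0),
      alter_has_sex_with_men = logical(0), alter_hiv_positive = logical(0),
      alter_exchange_sex = logical(0), alter_payment_received = logical(0),
      alter_partner_preference = character(0), stringsAsFactors = FALSE),
    matches = data.frame(
      ego_id = character(0), kind = character(0),
      nomination_id_earlier = character(0),
      nomination_id_later = character(0), wave_earlier = integer(0),
      wave_later = integer(0), stringsAsFactors = FALSE),
    attendance = data.frame(ego_id = character(0), wave = integer(0),
                            attended = logical(0), stringsAsFactors = FALSE))
}

test_that("empty tables validate to an empty dataset", {
  tb <- empty_tables()
  ds <- validate_dataset(tb$respondents, tb$rosters, tb$matches,
                         tb$attendance)
  expect_s3_class(ds, "netpanel_dataset")
  expect_identical(nrow(ds$violations), 0L)
})

test_that("cap, flag and referential violations are collected with coordinates", {
  ds0 <- build_panel(list(E1 = list(w1 = c("a", "b"), w2 = c("a"))))
  # confidant entry at position 6 -> cap violation
  bad <- ds0$rosters
  bad$position[1] <- 6L
  ds <- validate_dataset(ds0$respondents, bad, ds0$matches, ds0$attendance)
  expect_true(any(ds$violations$rule == "cap exceeded"))
  expect_identical(ds$violations$row[ds$violations$rule == "cap exceeded"],
                   1L)
  # cross-ego match
  ds2 <- build_panel(list(E1 = list(w1 = "a", w2 = "a"),
                          E2 = list(w1 = "z", w2 = "z")))
  m <- ds2$matches
  m$nomination_id_later[1] <- ds2$rosters$nomination_id[
    ds2$rosters$ego_id == "E2" & ds2$rosters$wave == 2][1]
  ds <- validate_dataset(ds2$respondents, ds2$rosters, m, ds2$attendance)
  expect_true(any(ds$violations$rule == "cross-ego match"))
  # primary flag on a confidant entry
  bad2 <- ds0$rosters
  bad2$is_primary_partner[1] <- TRUE
  ds <- validate_dataset(ds0$respondents, bad2, ds0$matches,
                         ds0$attendance)
  expect_true(any(ds$violations$rule == "primary flag"))
  # duplicate ego ids are a hard failure
  resp2 <- rbind(ds0$respondents, ds0$respondents)
  expect_error(validate_dataset(resp2, ds0$rosters, ds0$matches,
                                ds0$attendance), "duplicate ego_id")
})

test_that("alter resolution: singletons without matches, chains merge", {
  ds <- build_panel(list(E1 = list(w1 = c("a", "b", "c"))))
  map <- resolve_alters(ds)
  expect_identical(length(unique(map$map$alter_id)), 3L)
  # chain W1:a=W2:a, W2:a=W3:a -> single class covering all three waves
  ds3 <- build_panel(list(E1 = list(w1 = "a", w2 = "a", w3 = "a")))
  # build_panel links all earlier nominations; drop the W1-W3 record to
  # leave a pure chain and check transitivity (union-find oracle: one
  # class of 3)
  m <- ds3$matches[!(ds3$matches$wave_earlier == 1 &
                     ds3$matches$wave_later == 3), ]
  ds3b <- validate_dataset(ds3$respondents, ds3$rosters, m,
                           ds3$attendance)
  map3 <- resolve_alters(ds3b)
  expect_identical(length(unique(map3$map$alter_id)), 1L)
})

test_that("resolution is idempotent and order-independent", {
  ds <- build_panel(list(E1 = list(w1 = c("a", "b"), w2 = c("a", "b"),
                                   w3 = c("a", "c"))))
  ref <- resolve_alters(ds)
  partition <- function(map) {
    sp <- split(map$map$nomination_id, map$map$alter_id)
    unname(lapply(sp[order(vapply(sp, min, character(1)))], sort))
  }
  for (s in 1:5) {
    set.seed(s)
    shuf <- validate_dataset(ds$respondents, ds$rosters,
                             ds$matches[sample(nrow(ds$matches)), ],
                             ds$attendance)
    expect_identical(partition(resolve_alters(shuf)), partition(ref))
  }
})

test_that("a match chain merging two same-wave nominations is split and reported", {
  ds <- build_panel(list(E1 = list(w1 = c("a", "b"), w2 = "x")))
  # claim both W1 nominations match the single W2 nomination
  noms <- ds$rosters$nomination_id
  m <- data.frame(ego_id = "E1", kind = "confidant",
                  nomination_id_earlier = noms[1:2],
                  nomination_id_later = noms[3],
                  wave_earlier = 1L, wave_later = 2L,
                  stringsAsFactors = FALSE)
  ds2 <- validate_dataset(ds$respondents, ds$rosters, m, ds$attendance)
  map <- resolve_alters(ds2)
  expect_identical(nrow(map$inconsistencies), 1L)
  # the two W1 nominations stay distinct
  w1_ids <- map$map$alter_id[map$map$wave == 1]
  expect_identical(length(unique(w1_ids)), 2L)
})

test_that("perfect confirmations recover simulator ground truth exactly", {
  sim <- simulate_cohort(small_sim_config(rng_seed = 21, n_waves = 3))
  ds <- validate_dataset(sim)
  map <- resolve_alters(ds)
  truth <- setNames(sim$ground_truth$identity$member_id,
                    sim$ground_truth$identity$nomination_id)
  m <- map$map
  # within each ego and kind the resolved partition must equal the
  # partition induced by true member identity
  key <- paste(m$ego_id, m$kind)
  for (sub in split(m, key)) {
    expect_identical(
      as.integer(table(table(sub$alter_id))),
      as.integer(table(table(paste(truth[sub$nomination_id])))))
    agree <- tapply(truth[sub$nomination_id], sub$alter_id,
                    function(x) length(unique(x)))
    expect_true(all(agree == 1))
  }
})

test_that("identity recovery degrades monotonically with match dropout", {
  sim <- simulate_cohort(small_sim_config(rng_seed = 22, n_waves = 3))
  truth <- setNames(sim$ground_truth$identity$member_id,
                    sim$ground_truth$identity$nomination_id)
  # couple the dropout levels: one uniform draw per match record,
  # thresholded at increasing rates, gives nested confirmed subsets
  set.seed(99)
  u <- runif(nrow(sim$matches))
  recovered_pairs <- function(drop) {
    keep <- sim$matches[u >= drop, ]
    ds <- validate_dataset(sim$respondents, sim$rosters, keep,
                           sim$attendance)
    m <- resolve_alters(ds)$map
    # count within-ego-kind nomination pairs correctly identified as the
    # same alter
    total <- 0
    for (sub in split(m, paste(m$ego_id, m$kind))) {
      same_res <- outer(sub$alter_id, sub$alter_id, "==")
      same_tru <- outer(truth[sub$nomination_id], truth[sub$nomination_id],
                        "==")
      total <- total + sum(same_res & same_tru & upper.tri(same_res))
    }
    total
  }
  rec <- vapply(c(0, 0.4, 0.8), recovered_pairs, numeric(1))
  expect_true(all(diff(rec) <= 0))
  expect_gt(rec[1], rec[3])
})

test_that("roster sets deduplicate, include the primary, and flag absent visits", {
  ds <- build_panel(list(E1 = list(w1 = c("a", "b", "c", "d", "e"))))
  expect_identical(length(roster_set(ds, "E1", 1, "confidant")), 5L)
  expect_error(roster_set(ds, "E1", 2, "confidant"),
               class = "netpanel_absent_visit")
  # primary partner listed among the recent five: set of 5, not 6
  ros <- data.frame(
    ego_id = "E2", wave = 1L, kind = "sexual",
    nomination_id = paste0("E2.w1.s", 1:5), position = 1:5,
    is_primary_partner = c(TRUE, rep(FALSE, 4)),
    alter_gender = "man", alter_has_sex_with_men = TRUE,
    alter_hiv_positive = NA, alter_exchange_sex = FALSE,
    alter_payment_received = FALSE, alter_partner_preference = "men",
    stringsAsFactors = FALSE)
  resp <- data.frame(ego_id = "E2", group = "MSM", age_years = 22,
                     hiv_positive = NA, employed = NA, income_lt_20k = NA,
                     stably_housed = NA, ever_jail = NA, insured = NA,
                     in_relationship = NA, stringsAsFactors = FALSE)
  att <- data.frame(ego_id = "E2", wave = 1L, attended = TRUE,
                    stringsAsFactors = FALSE)
  ds2 <- validate_dataset(resp, ros, empty_tables()$matches, att)
  expect_identical(nrow(ds2$violations), 0L)
  expect_identical(length(roster_set(ds2, "E2", 1, "sexual")), 5L)
})

test_that("resolved roster sets never exceed the caps", {
  sim <- simulate_cohort(small_sim_config(rng_seed = 31, n_waves = 3,
                                          mean_confidant_degree = 10,
                                          mean_sexual_degree = 7))
  ds <- validate_dataset(sim)
  map <- resolve_alters(ds)
  m <- map$map
  sizes <- tapply(m$alter_id, paste(m$ego_id, m$wave, m$kind),
                  function(x) length(unique(x)))
  kinds <- sub(".* ", "", names(sizes))
  expect_true(all(sizes[kinds == "confidant"] <= 5))
  expect_true(all(sizes[kinds == "sexual"] <= 6))
})
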