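ROSTER_CAPS <- c(confidant = 5L, sexual = 6L)
SEXUAL_RECENT_CAP <- 5L

# Per-ego tie state: state[[kind]][[ego_id]] is a data.frame with columns
# alter (member_id), exchange_sex, payment_received, created_wave.
new_tie_rows <- function(kind, ego_group, alters, wave, config) {
  k <- length(alters)
  if (kind == "sexual" && k > 0) {
    ex <- stats::runif(k) < config$alter_attr$exchange_sex[[ego_group]]
    pay <- stats::runif(k) < config$alter_attr$payment_received[[ego_group]]
  } else {
    ex <- rep(NA, k); pay <- rep(NA, k)
  }
  data.frame(alter = alters, exchange_sex = ex, payment_received = pay,
             created_wave = rep(wave, k), stringsAsFactors = FALSE)
}

#' Initialize per-ego tie state for the enrolled sample at Wave 1
#'
#' Projects the population's undirected tie structures onto each enrolled
#' ego's personal roster pool and, for sexual ties, attaches external-pool
#' partners at the configured per-group rate.
#'
#' @param population a [generate_population()] result.
#' @param sample_ids character vector of enrolled ego ids.
#' @param config a [sim_config()] object.
#' @return tie state list (`confidant`, `sexual`), each a named list of
#'   per-ego data frames.
#' @export
init_sample_ties <- function(population, sample_ids, config) {
  config <- validate_sim_config(config)
  set.seed(stream_seed(config$rng_seed, "dynamics"))
  members <- population$members
  grp <- stats::setNames(members$group, members$member_id)
  ext_ids <- members$member_id[members$stratum == "external"]
  state <- list()
  for (kind in c("confidant", "sexual")) {
    edges <- population$ties[[kind]]
    nbr <- make_adjacency(unique(c(edges$i, edges$j, sample_ids)), edges)
    st <- stats::setNames(vector("list", length(sample_ids)), sample_ids)
    for (ego in sample_ids) {
      alters <- sort(nbr[[ego]] %||% character(0))
      if (kind == "sexual" && length(ext_ids) > 0) {
        lam <- config$prop_external_partner[[grp[[ego]]]] *
          config$mean_sexual_degree
        n_ext <- stats::rpois(1, lam)
        if (n_ext > 0)
          alters <- c(alters, sample(ext_ids, min(n_ext, length(ext_ids))))
      }
      st[[ego]] <- new_tie_rows(kind, grp[[ego]], alters, 1L, config)
    }
    state[[kind]] <- st
  }
  state
}

#' Evolve per-ego tie sets to the next wave
#'
#' Each existing tie persists independently with
#' `retain_prob[[kind]][ego_group]`; new ties arrive per ego as a Poisson
#' draw with mean `new_tie_rate[[kind]][ego_group]`, attached to eligible
#' partners not currently tied (sexual ties attach to the external pool
#' with the configured per-group probability). Previously lost partners
#' are eligible again, so a tie can be regained.
#'
#' @param state tie state from [init_sample_ties()] or a previous call.
#' @param population a [generate_population()] result.
#' @param config a [sim_config()] object.
#' @param from_wave the wave the state currently describes.
#' @return list with `state` (tie state at `from_wave + 1`) and `events`
#'   (ground-truth data frame: one row per tie present at `from_wave` with
#'   its `persisted` outcome).
#' @export
evolve_ties <- function(state, population, config, from_wave) {
  config <- validate_sim_config(config)
  set.seed(stream_seed(config$rng_seed, "dynamics") + 131L * from_wave)
  members <- population$members
  grp <- stats::setNames(members$group, members$member_id)
  pop_ids <- members$member_id[members$stratum == "population"]
  ext_ids <- members$member_id[members$stratum == "external"]
  events <- list()
  nxt <- list()
  for (kind in c("confidant", "sexual")) {
    st <- state[[kind]]
    out <- st
    for (ego in names(st)) {
      g <- grp[[ego]]
      cur <- st[[ego]]
      keep <- if (nrow(cur) > 0)
        stats::runif(nrow(cur)) < config$retain_prob[[kind]][[g]]
      else logical(0)
      if (nrow(cur) > 0)
        events[[length(events) + 1L]] <- data.frame(
          ego_id = ego, kind = kind, alter = cur$alter,
          group = g, from_wave = from_wave, persisted = keep,
          stringsAsFactors = FALSE)
      new_state <- cur[keep, , drop = FALSE]
      n_new <- stats::rpois(1, config$new_tie_rate[[kind]][[g]])
      if (n_new > 0) {
        use_ext <- kind == "sexual" & length(ext_ids) > 0 &
          stats::runif(n_new) < config$prop_external_partner[[g]]
        pools <- list(pop_ids[pop_ids != ego], ext_ids)
        picked <- character(0)
        for (ext in c(FALSE, TRUE)) {
          want <- sum(use_ext == ext)
          if (want == 0) next
          cand <- setdiff(pools[[ext + 1L]], new_state$alter)
          if (length(cand) > 0)
            picked <- c(picked, sample(cand, min(want, length(cand))))
        }
        picked <- setdiff(unique(picked), new_state$alter)
        if (length(picked) > 0)
          new_state <- rbind(new_state,
                             new_tie_rows(kind, g, picked,
                                          from_wave + 1L, config))
      }
      rownames(new_state) <- NULL
      out[[ego]] <- new_state
    }
    nxt[[kind]] <- out
  }
  list(state = nxt,
       events = if (length(events)) do.call(rbind, events)
                else data.frame(ego_id = character(0), kind = character(0),
                                alter = character(0), group = character(0),
                                from_wave = integer(0),
                                persisted = logical(0)))
}

#' Emit one wave's roster, attendance and identity tables
#'
#' Attendance at Wave 1 is universal; at later waves each ego attends with
#' the per-group retention probability (Bernoulli, independent across
#' waves, so an ego can miss Wave 2 and return at Wave 3). For each
#' attending ego the confidant roster lists up to five current confidant
#' ties (a uniform subsample when over the cap) and the sexual roster up
#' to five recent partners; with the configured probability a primary
#' partner is designated from all current sexual ties (the previous
#' wave's primary is kept while the tie lasts) and appears either as a
#' flag on a listed entry or as a sixth entry.
#'
#' @param population a [generate_population()] result.
#' @param sample_ids enrolled ego ids.
#' @param state tie state for this wave.
#' @param wave 1-based wave index.
#' @param config a [sim_config()] object.
#' @param primary_prev named character vector (ego -> previous primary
#'   partner member id), or `NULL` at Wave 1.
#' @return list with `rosters` (emitted roster rows), `identity`
#'   (nomination_id -> true member id; simulator ground truth),
#'   `attendance` (ego_id, wave, attended) and `primary` (state for the
#'   next wave).
#' @export
emit_wave_tables <- function(population, sample_ids, state, wave, config,
                             primary_prev = NULL) {
  config <- validate_sim_config(config)
  set.seed(stream_seed(config$rng_seed, "emission") + 131L * wave)
  members <- population$members
  rownames(members) <- members$member_id
  grp <- stats::setNames(members$group, members$member_id)

  if (wave == 1L) {
    attended <- rep(TRUE, length(sample_ids))
  } else {
    attended <- stats::runif(length(sample_ids)) <
      config$attrition_retention[grp[sample_ids]]
  }
  attendance <- data.frame(ego_id = sample_ids, wave = wave,
                           attended = attended, stringsAsFactors = FALSE)

  acc <- list(ego = character(0), kind = character(0),
              alter = character(0), pos = integer(0), prim = logical(0),
              ex = logical(0), pay = logical(0))
  push <- function(ego, kind, alter, prim, ex, pay) {
    acc$ego <<- c(acc$ego, rep(ego, length(alter)))
    acc$kind <<- c(acc$kind, rep(kind, length(alter)))
    acc$alter <<- c(acc$alter, alter)
    acc$pos <<- c(acc$pos, seq_along(alter))
    acc$prim <<- c(acc$prim, prim)
    acc$ex <<- c(acc$ex, ex)
    acc$pay <<- c(acc$pay, pay)
  }
  primary_now <- stats::setNames(rep(NA_character_, length(sample_ids)),
                                 sample_ids)
  for (ego in sample_ids[attended]) {
    for (kind in c("confidant", "sexual")) {
      cur <- state[[kind]][[ego]]
      if (is.null(cur) || nrow(cur) == 0) next
      cap <- if (kind == "confidant") ROSTER_CAPS[["confidant"]]
             else SEXUAL_RECENT_CAP
      listed <- if (nrow(cur) > cap)
        cur[sort(sample.int(nrow(cur), cap)), , drop = FALSE]
      else cur
      prim_alter <- NA_character_
      if (kind == "sexual") {
        prev <- if (!is.null(primary_prev)) primary_prev[[ego]]
                else NA_character_
        if (!is.na(prev) && prev %in% cur$alter) {
          prim_alter <- prev
        } else if (stats::runif(1) < config$primary_partner_prob) {
          prim_alter <- sample(cur$alter, 1)
        }
        primary_now[[ego]] <- prim_alter
        if (!is.na(prim_alter) && !(prim_alter %in% listed$alter))
          listed <- rbind(listed,
                          cur[cur$alter == prim_alter, , drop = FALSE])
      }
      push(ego, kind, listed$alter,
           if (kind == "sexual") !is.na(prim_alter) &
             listed$alter == prim_alter
           else rep(FALSE, nrow(listed)),
           listed$exchange_sex, listed$payment_received)
    }
  }
  nom <- sprintf("%s.w%d.%s%d", acc$ego, wave, substr(acc$kind, 1, 1),
                 acc$pos)
  am <- members[acc$alter, , drop = FALSE]
  hiv_known <- stats::runif(length(nom)) < config$alter_attr$hiv_known_prob
  rosters <- data.frame(
    ego_id = acc$ego, wave = rep(wave, length(nom)), kind = acc$kind,
    nomination_id = nom, position = acc$pos,
    is_primary_partner = acc$prim,
    alter_gender = am$gender,
    alter_has_sex_with_men = am$has_sex_with_men,
    alter_hiv_positive = ifelse(hiv_known, am$hiv_positive, NA),
    alter_exchange_sex = acc$ex,
    alter_payment_received = acc$pay,
    alter_partner_preference = am$partner_preference,
    stringsAsFactors = FALSE)
  rownames(rosters) <- NULL
  list(rosters = rosters,
       identity = data.frame(nomination_id = nom, member_id = acc$alter,
                             stringsAsFactors = FALSE),
       attendance = attendance,
       primary = primary_now)
}

# Respondent-confirmed match records from emitted rosters plus ground-truth
# identity. Cross-wave (within kind): every earlier/later nomination pair
# of the same true alter by the same ego (the Wave-3 confirmation list is
# cumulative over Waves 1-2, so all earlier waves are linkable). Overlap
# (cross-kind, same wave): one record linking a confidant nomination to a
# sexual nomination of the same person. Each record independently drops
# with probability `match_dropout` (imperfect confirmation).
build_match_records <- function(rosters, identity, config) {
  set.seed(stream_seed(config$rng_seed, "emission") + 999983L)
  rid <- merge(rosters[, c("ego_id", "wave", "kind", "nomination_id")],
               identity, by = "nomination_id")
  out <- list()
  for (kind in c("confidant", "sexual")) {
    rk <- rid[rid$kind == kind, ]
    rk <- rk[order(rk$ego_id, rk$member_id, rk$wave, rk$nomination_id), ]
    key <- paste(rk$ego_id, rk$member_id)
    ego_v <- character(0); a_v <- character(0); b_v <- character(0)
    wa_v <- integer(0); wb_v <- integer(0)
    for (grp_rows in split(seq_len(nrow(rk)), key)) {
      if (length(grp_rows) < 2) next
      cmb <- utils::combn(grp_rows, 2)
      keep <- rk$wave[cmb[1, ]] < rk$wave[cmb[2, ]]
      if (!any(keep)) next
      ego_v <- c(ego_v, rep(rk$ego_id[grp_rows[1]], sum(keep)))
      a_v <- c(a_v, rk$nomination_id[cmb[1, keep]])
      b_v <- c(b_v, rk$nomination_id[cmb[2, keep]])
      wa_v <- c(wa_v, rk$wave[cmb[1, keep]])
      wb_v <- c(wb_v, rk$wave[cmb[2, keep]])
    }
    if (length(ego_v) > 0)
      out[[length(out) + 1L]] <- data.frame(
        ego_id = ego_v, kind = kind,
        nomination_id_earlier = a_v, nomination_id_later = b_v,
        wave_earlier = wa_v, wave_later = wb_v, stringsAsFactors = FALSE)
  }
  # same-wave confidant/sexual overlap confirmations
  for (w in sort(unique(rid$wave))) {
    rw <- rid[rid$wave == w, ]
    cf <- rw[rw$kind == "confidant", ]
    sx <- rw[rw$kind == "sexual", ]
    ov <- merge(cf, sx, by = c("ego_id", "member_id"))
    if (nrow(ov) > 0)
      out[[length(out) + 1L]] <- data.frame(
        ego_id = ov$ego_id, kind = "overlap",
        nomination_id_earlier = ov$nomination_id.x,
        nomination_id_later = ov$nomination_id.y,
        wave_earlier = w, wave_later = w, stringsAsFactors = FALSE)
  }
  matches <- if (length(out)) do.call(rbind, out)
             else data.frame(ego_id = character(0), kind = character(0),
                             nomination_id_earlier = character(0),
                             nomination_id_later = character(0),
                             wave_earlier = integer(0),
                             wave_later = integer(0),
                             stringsAsFactors = FALSE)
  if (config$match_dropout > 0 && nrow(matches) > 0)
    matches <- matches[stats::runif(nrow(matches)) >= config$match_dropout,
                       , drop = FALSE]
  matches <- matches[order(matches$ego_id, matches$kind,
                           matches$nomination_id_earlier,
                           matches$nomination_id_later), , drop = FALSE]
  rownames(matches) <- NULL
  matches
}

#' Simulate a full RDS network cohort with ground truth
#'
#' Runs the whole generative chain — hidden population, seeded RDS
#' recruitment, per-wave tie evolution, attendance with differential
#' attrition, capped roster emission, and respondent-confirmed cross-wave
#' and cross-kind match records — and returns both the observable tables
#' (respondents, rosters, matches, attendance) and the synthetic-only
#' ground truth (true nomination identities, per-tie persistence events,
#' realized retention fractions).
#'
#' @param config a [sim_config()] object.
#' @return an object of class `netpanel_sim`: the four observable tables,
#'   a `ground_truth` list and the `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  config <- validate_sim_config(config)
  population <- generate_population(config)
  rec <- run_rds_recruitment(population, config)
  sample_ids <- rec$sample$ego_id
  state <- init_sample_ties(population, sample_ids, config)

  rosters <- list(); identity <- list(); attendance <- list()
  events <- list()
  primary <- NULL
  for (w in seq_len(config$n_waves)) {
    if (w > 1) {
      ev <- evolve_ties(state, population, config, from_wave = w - 1L)
      state <- ev$state
      events[[length(events) + 1L]] <- ev$events
    }
    em <- emit_wave_tables(population, sample_ids, state, w, config,
                           primary_prev = primary)
    rosters[[w]] <- em$rosters
    identity[[w]] <- em$identity
    attendance[[w]] <- em$attendance
    primary <- em$primary
  }
  rosters <- do.call(rbind, rosters)
  identity <- do.call(rbind, identity)
  attendance <- do.call(rbind, attendance)
  # rosters describe attended visits only; drop any rows from non-attended
  # visits defensively (emission already restricts to attendees)
  matches <- build_match_records(rosters, identity, config)

  members <- population$members
  rownames(members) <- members$member_id
  em <- members[sample_ids, ]
  respondents <- data.frame(
    ego_id = em$member_id, group = em$group, age_years = em$age_years,
    hiv_positive = em$hiv_positive, employed = em$employed,
    income_lt_20k = em$income_lt_20k, stably_housed = em$stably_housed,
    ever_jail = em$ever_jail, insured = em$insured,
    in_relationship = em$in_relationship,
    n_partners_6mo = em$n_partners_6mo,
    stringsAsFactors = FALSE)
  ori <- em$orientation
  for (w in seq_len(config$n_waves))
    respondents[[sprintf("orientation_w%d", w)]] <- ori[, w]
  respondents$recruiter_id <- rec$sample$recruiter_id
  respondents$wave_of_entry <- rec$sample$wave_of_entry
  rownames(respondents) <- NULL

  events <- if (length(events)) do.call(rbind, events)
            else data.frame(ego_id = character(0), kind = character(0),
                            alter = character(0), group = character(0),
                            from_wave = integer(0), persisted = logical(0))
  realized <- if (nrow(events) > 0)
    stats::aggregate(persisted ~ kind + group, data = events, FUN = mean)
  else NULL

  structure(list(
    respondents = respondents, rosters = rosters, matches = matches,
    attendance = attendance,
    ground_truth = list(identity = identity, events = events,
                        realized_retention = realized,
                        population = population, recruitment = rec),
    config = config),
    class = "netpanel_sim")
}
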