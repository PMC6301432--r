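ROSTER_COLUMNS <- c("ego_id", "wave", "kind", "nomination_id", "position",
                    "is_primary_partner", "alter_gender",
                    "alter_has_sex_with_men", "alter_hiv_positive",
                    "alter_exchange_sex", "alter_payment_received",
                    "alter_partner_preference")
MATCH_COLUMNS <- c("ego_id", "kind", "nomination_id_earlier",
                   "nomination_id_later", "wave_earlier", "wave_later")
ATTENDANCE_COLUMNS <- c("ego_id", "wave", "attended")
RESPONDENT_CORE_COLUMNS <- c("ego_id", "group", "age_years", "hiv_positive",
                             "employed", "income_lt_20k", "stably_housed",
                             "ever_jail", "insured", "in_relationship")

#' Validate a longitudinal roster dataset
#'
#' Checks referential integrity and the roster-model invariants: every
#' roster and attendance ego is enrolled, roster rows belong to attended
#' ego-waves, positions respect the per-kind caps (5 confidant entries; 6
#' sexual entries including the primary partner), primary-partner flags
#' are sexual-only and unique per ego-wave, and every match references two
#' existing nominations of the same ego (same kind for cross-wave matches
#' with `wave_earlier < wave_later`; a confidant and a sexual nomination
#' at the same wave for `overlap` records). Duplicate ego ids are a hard
#' failure; all other violations are collected into a report with row
#' coordinates.
#'
#' @param respondents,rosters,matches,attendance the four data-model
#'   tables (see [read_tables()] for the documented headers), or a single
#'   `netpanel_sim` object in `respondents`.
#' @return an object of class `netpanel_dataset`: the tables plus a
#'   `violations` data frame (zero rows when valid) and `n_waves`.
#' @export
validate_dataset <- function(respondents, rosters = NULL, matches = NULL,
                             attendance = NULL) {
  if (inherits(respondents, "netpanel_sim")) {
    sim <- respondents
    return(validate_dataset(sim$respondents, sim$rosters, sim$matches,
                            sim$attendance))
  }
  viol <- list()
  note <- function(table, row, rule, msg) {
    viol[[length(viol) + 1L]] <<- data.frame(
      table = table, row = row, rule = rule, message = msg,
      stringsAsFactors = FALSE)
  }
  if (anyDuplicated(respondents$ego_id))
    stop("duplicate ego_ids in respondents table", call. = FALSE)
  egos <- respondents$ego_id
  n_waves <- max(1L, attendance$wave, rosters$wave)

  bad_group <- which(!respondents$group %in% c("TGW", "MSM"))
  for (r in bad_group)
    note("respondents", r, "group",
         sprintf("unknown group '%s'", respondents$group[r]))

  att_key <- paste(attendance$ego_id[attendance$attended],
                   attendance$wave[attendance$attended])
  for (r in which(!attendance$ego_id %in% egos))
    note("attendance", r, "unenrolled ego",
         sprintf("ego '%s' not enrolled", attendance$ego_id[r]))

  if (nrow(rosters) > 0) {
    for (r in which(!rosters$ego_id %in% egos))
      note("rosters", r, "unenrolled ego",
           sprintf("ego '%s' not enrolled", rosters$ego_id[r]))
    for (r in which(!paste(rosters$ego_id, rosters$wave) %in% att_key))
      note("rosters", r, "absent visit",
           sprintf("roster row for ego '%s' at non-attended wave %d",
                   rosters$ego_id[r], rosters$wave[r]))
    cap <- ROSTER_CAPS[rosters$kind]
    for (r in which(is.na(cap)))
      note("rosters", r, "kind", sprintf("unknown kind '%s'",
                                         rosters$kind[r]))
    for (r in which(!is.na(cap) &
                    (rosters$position < 1 | rosters$position > cap)))
      note("rosters", r, "cap exceeded",
           sprintf("position %d exceeds the %s cap of %d",
                   rosters$position[r], rosters$kind[r], cap[r]))
    for (r in which(rosters$kind == "confidant" &
                    rosters$is_primary_partner))
      note("rosters", r, "primary flag",
           "is_primary_partner set on a confidant entry")
    sx <- rosters[rosters$kind == "sexual" & rosters$is_primary_partner, ]
    if (nrow(sx) > 0) {
      dup <- names(which(table(paste(sx$ego_id, sx$wave)) > 1))
      for (d in dup)
        note("rosters", NA_integer_, "primary flag",
             sprintf("multiple primary partners for ego-wave '%s'", d))
    }
    if (anyDuplicated(rosters$nomination_id))
      note("rosters", anyDuplicated(rosters$nomination_id),
           "nomination id", "duplicate nomination_id")
  }

  if (nrow(matches) > 0) {
    nom_ego <- stats::setNames(rosters$ego_id, rosters$nomination_id)
    nom_kind <- stats::setNames(rosters$kind, rosters$nomination_id)
    nom_wave <- stats::setNames(rosters$wave, rosters$nomination_id)
    for (r in seq_len(nrow(matches))) {
      a <- matches$nomination_id_earlier[r]
      b <- matches$nomination_id_later[r]
      if (!a %in% names(nom_ego) || !b %in% names(nom_ego)) {
        note("matches", r, "missing nomination",
             "match references a nomination that does not exist")
        next
      }
      if (nom_ego[[a]] != nom_ego[[b]] ||
          matches$ego_id[r] != nom_ego[[a]]) {
        note("matches", r, "cross-ego match",
             "match links nominations of different egos")
        next
      }
      if (matches$kind[r] == "overlap") {
        if (nom_kind[[a]] == nom_kind[[b]])
          note("matches", r, "overlap kind",
               "overlap match must link a confidant and a sexual entry")
        if (nom_wave[[a]] != nom_wave[[b]])
          note("matches", r, "overlap wave",
               "overlap match must link nominations at the same wave")
      } else {
        if (nom_kind[[a]] != matches$kind[r] ||
            nom_kind[[b]] != matches$kind[r])
          note("matches", r, "kind mismatch",
               "match kind disagrees with its nominations")
        if (!(matches$wave_earlier[r] < matches$wave_later[r]) ||
            nom_wave[[a]] != matches$wave_earlier[r] ||
            nom_wave[[b]] != matches$wave_later[r])
          note("matches", r, "wave order",
               "cross-wave match must run from an earlier to a later wave")
      }
    }
  }

  violations <- if (length(viol)) do.call(rbind, viol)
                else data.frame(table = character(0), row = integer(0),
                                rule = character(0), message = character(0),
                                stringsAsFactors = FALSE)
  structure(list(respondents = respondents, rosters = rosters,
                 matches = matches, attendance = attendance,
                 violations = violations, n_waves = n_waves),
            class = "netpanel_dataset")
}

#' @export
print.netpanel_dataset <- function(x, ...) {
  cat(sprintf(
    "<netpanel_dataset> %d respondents, %d roster rows, %d matches, %d waves",
    nrow(x$respondents), nrow(x$rosters), nrow(x$matches), x$n_waves))
  if (nrow(x$violations) > 0)
    cat(sprintf(" [%d validation violations]", nrow(x$violations)))
  cat("\n")
  invisible(x)
}

#' Resolve alter identities across waves from confirmed matches
#'
#' Builds, per ego and roster kind, the equivalence classes of nominations
#' implied by the respondent-confirmed cross-wave match records (their
#' transitive closure), labelling each class by its lexicographically
#' smallest nomination id. Unmatched nominations become singleton alters.
#' A match chain that would merge two nominations made at the same wave is
#' inconsistent (one interview lists distinct people): the offending union
#' is refused — earlier-wave links take priority because matches are
#' processed in wave order — and reported. Cross-kind `overlap` records
#' never merge ids across kinds; they are returned as a separate overlap
#' table.
#'
#' @param dataset a `netpanel_dataset`.
#' @return a list of class `netpanel_alter_map`: `map` (nomination_id,
#'   ego_id, kind, wave, position, alter_id), `overlap` (per ego-wave
#'   pairs of confidant/sexual alter ids confirmed to be the same person)
#'   and `inconsistencies`.
#' @export
resolve_alters <- function(dataset) {
  rosters <- dataset$rosters
  matches <- dataset$matches
  map <- rosters[, c("nomination_id", "ego_id", "kind", "wave", "position")]
  parent <- stats::setNames(map$nomination_id, map$nomination_id)
  waves <- stats::setNames(map$wave, map$nomination_id)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  class_waves <- split(map$wave, map$nomination_id)  # waves present per class
  inconsistent <- list()
  cw <- matches[matches$kind %in% c("confidant", "sexual"), , drop = FALSE]
  if (nrow(cw) > 0) {
    cw <- cw[order(cw$wave_later, cw$wave_earlier, cw$nomination_id_earlier,
                   cw$nomination_id_later), ]
    for (r in seq_len(nrow(cw))) {
      a <- cw$nomination_id_earlier[r]; b <- cw$nomination_id_later[r]
      if (!a %in% names(parent) || !b %in% names(parent)) next
      ra <- find(a); rb <- find(b)
      if (ra == rb) next
      if (length(intersect(class_waves[[ra]], class_waves[[rb]])) > 0) {
        inconsistent[[length(inconsistent) + 1L]] <- data.frame(
          ego_id = cw$ego_id[r], kind = cw$kind[r],
          nomination_id_earlier = a, nomination_id_later = b,
          reason = "merge would identify two same-wave nominations",
          stringsAsFactors = FALSE)
        next
      }
      root <- min(ra, rb); other <- max(ra, rb)
      parent[[other]] <- root
      class_waves[[root]] <- c(class_waves[[root]], class_waves[[other]])
      class_waves[[other]] <- NULL
    }
  }
  map$alter_id <- if (nrow(map) > 0)
    vapply(map$nomination_id, find, character(1)) else character(0)

  ov <- matches[matches$kind == "overlap", , drop = FALSE]
  alter_of <- stats::setNames(map$alter_id, map$nomination_id)
  overlap <- if (nrow(ov) > 0) {
    keep <- ov$nomination_id_earlier %in% names(alter_of) &
      ov$nomination_id_later %in% names(alter_of)
    ov <- ov[keep, , drop = FALSE]
    unique(data.frame(
      ego_id = ov$ego_id, wave = ov$wave_earlier,
      alter_id_confidant = unname(alter_of[ov$nomination_id_earlier]),
      alter_id_sexual = unname(alter_of[ov$nomination_id_later]),
      stringsAsFactors = FALSE))
  } else data.frame(ego_id = character(0), wave = integer(0),
                    alter_id_confidant = character(0),
                    alter_id_sexual = character(0),
                    stringsAsFactors = FALSE)
  structure(list(
    map = map, overlap = overlap,
    inconsistencies = if (length(inconsistent)) do.call(rbind, inconsistent)
                      else data.frame(ego_id = character(0),
                                      kind = character(0),
                                      nomination_id_earlier = character(0),
                                      nomination_id_later = character(0),
                                      reason = character(0),
                                      stringsAsFactors = FALSE)),
    class = "netpanel_alter_map")
}

#' The set of distinct alters an ego nominated at a wave
#'
#' Returns the deduplicated alter ids (after identity resolution) of one
#' ego's roster of one kind at one wave; the primary sexual partner is
#' part of the sexual set (so an ego listing the primary among the five
#' recent partners has a set of five, not six). Querying a wave the ego
#' did not attend raises a classed `netpanel_absent_visit` error — an
#' absent visit is not an empty roster.
#'
#' @param dataset a `netpanel_dataset`.
#' @param ego ego id.
#' @param wave 1-based wave index.
#' @param kind `"confidant"` or `"sexual"`.
#' @param map optional precomputed [resolve_alters()] result.
#' @return character vector of alter ids (possibly empty).
#' @export
roster_set <- function(dataset, ego, wave, kind, map = NULL) {
  att <- dataset$attendance
  ok <- any(att$ego_id == ego & att$wave == wave & att$attended)
  if (!ok)
    stop(new_condition(
      sprintf("ego '%s' did not attend wave %d", ego, wave),
      "netpanel_absent_visit"))
  map <- map %||% resolve_alters(dataset)
  m <- map$map
  sort(unique(m$alter_id[m$ego_id == ego & m$wave == wave &
                         m$kind == kind]))
}
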