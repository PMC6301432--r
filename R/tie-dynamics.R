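#' Classify one ego's ties as retained, lost or new across study visits
#'
#' Over the ego's ordered attended visits `v1..vk` (non-consecutive
#' attendance uses the attended sequence as-is): the original network is
#' the first visit's roster set (size `O`); a tie is *retained* when an
#' original alter is present at every subsequent attended visit (the
#' default strict rule) or at any later visit (`retained_rule =
#' "any_later"`); a tie is *new* when the alter first appears after `v1`
#' (counted once); each disappearance of an original-network alter
#' between consecutive attended visits counts one *lost* tie, so a tie
#' lost and later regained contributes one loss and no new tie (the
#' alter is already in the cumulative set), while a transient new tie
#' enters the turnover ratio only through the cumulative size (this is
#' what keeps turnover within `[0, 1]`). The cumulative network size `C`
#' is the number of distinct alters over all attended visits, so
#' `C = O + N`.
#'
#' @param dataset a `netpanel_dataset`.
#' @param ego ego id.
#' @param kind `"confidant"` or `"sexual"`.
#' @param map optional precomputed [resolve_alters()] result.
#' @param retained_rule `"strict"` (present at every later attended
#'   visit) or `"any_later"`.
#' @return a list with `eligible` (`FALSE`, with a `reason`, for egos
#'   with fewer than two attended visits — such egos are excluded, never
#'   scored zero), `summary` (one-row data frame: `O`, `R`, `L`, `N`,
#'   `C`, `n_visits`, `stability`, `turnover`) and `alters` (per-alter
#'   status records).
#' @export
classify_ties <- function(dataset, ego, kind, map = NULL,
                          retained_rule = c("strict", "any_later")) {
  retained_rule <- match.arg(retained_rule)
  att <- dataset$attendance
  waves <- sort(att$wave[att$ego_id == ego & att$attended])
  if (length(waves) < 2)
    return(list(eligible = FALSE,
                reason = "fewer than two attended visits",
                summary = NULL, alters = NULL))
  map <- map %||% resolve_alters(dataset)
  m <- map$map[map$map$ego_id == ego & map$map$kind == kind, ]
  sets <- lapply(waves, function(w) unique(m$alter_id[m$wave == w]))
  core <- classify_roster_sets(sets, retained_rule)
  all_ids <- core$all_ids
  first_wave <- vapply(all_ids, function(a)
    waves[min(which(vapply(sets, function(s) a %in% s, logical(1))))],
    numeric(1))
  alters <- data.frame(
    alter_id = all_ids,
    first_wave = first_wave,
    is_new = !(all_ids %in% sets[[1]]),
    is_retained = all_ids %in% core$retained,
    n_losses = as.integer(if (length(all_ids)) core$losses[all_ids]
                          else integer(0)),
    stringsAsFactors = FALSE)
  summary <- cbind(data.frame(ego_id = ego, kind = kind,
                              stringsAsFactors = FALSE), core$summary)
  list(eligible = TRUE, reason = NA_character_, summary = summary,
       alters = alters)
}

# Classification core over an ordered list of per-visit roster sets.
classify_roster_sets <- function(sets, retained_rule) {
  original <- sets[[1]]
  all_ids <- unique(unlist(sets))
  O <- length(original)
  C <- length(all_ids)
  retained <- if (O == 0) character(0)
  else if (retained_rule == "strict")
    original[vapply(original, function(a)
      all(vapply(sets[-1], function(s) a %in% s, logical(1))), logical(1))]
  else
    original[vapply(original, function(a)
      any(vapply(sets[-1], function(s) a %in% s, logical(1))), logical(1))]
  R <- length(retained)
  N <- C - O
  losses <- stats::setNames(integer(length(all_ids)), all_ids)
  if (length(sets) > 1) {
    for (t in seq_len(length(sets) - 1)) {
      # losses are disappearances of original-network ties between
      # consecutive attended visits; a transient new tie contributes to
      # the cumulative size (hence to turnover through N/C) but not to L,
      # which keeps turnover within [0, 1] (up to three visits, an
      # original tie can disappear at most once)
      gone <- intersect(setdiff(sets[[t]], sets[[t + 1]]), original)
      losses[gone] <- losses[gone] + 1L
    }
  }
  L <- sum(losses)
  list(summary = data.frame(
         O = O, R = R, L = L, N = N, C = C, n_visits = length(sets),
         stability = if (O > 0) R / O else NA_real_,
         turnover = if (C > 0) (N + L) / C else NA_real_,
         stringsAsFactors = FALSE),
       retained = retained, losses = losses, all_ids = all_ids)
}

#' Stability ratio: retained ties over original network size
#'
#' @param summary a one-row tie-change summary (from [classify_ties()] or
#'   a row of [cohort_dynamics()] output) with columns `R` and `O`.
#' @return `R / O`; `NA` with a `"undefined_ratio"` attribute when
#'   `O = 0` (such egos are excluded from group means, with the reason
#'   logged).
#' @export
stability_ratio <- function(summary) {
  if (summary$O == 0) {
    out <- NA_real_
    attr(out, "undefined_ratio") <- "original network size is zero"
    return(out)
  }
  summary$R / summary$O
}

#' Turnover ratio: new plus lost ties over cumulative network size
#'
#' For an ego with exactly two visits this equals `1 - R/C` exactly.
#'
#' @param summary a one-row tie-change summary with columns `N`, `L`, `C`.
#' @return `(N + L) / C`; `NA` with a `"undefined_ratio"` attribute when
#'   `C = 0`.
#' @export
turnover_ratio <- function(summary) {
  if (summary$C == 0) {
    out <- NA_real_
    attr(out, "undefined_ratio") <- "cumulative network size is zero"
    return(out)
  }
  (summary$N + summary$L) / summary$C
}

#' Cohort-level tie dynamics with group comparisons
#'
#' Computes one tie-change summary per eligible ego (two or more attended
#' visits) per roster kind, then compares TGW and MSM group means of the
#' stability and turnover ratios with a two-sided independent t-test
#' (Welch by default).
#'
#' @param dataset a `netpanel_dataset`.
#' @param retained_rule see [classify_ties()].
#' @param ttest `"welch"` (unequal variances) or `"pooled"`.
#' @param map optional precomputed [resolve_alters()] result.
#' @return a list of class `netpanel_dynamics`: `summaries` (one row per
#'   ego x kind), `comparisons` (one row per kind x ratio: group means,
#'   n, t, p, flags) and `exclusions` (egos excluded, with reasons).
#' @export
cohort_dynamics <- function(dataset, retained_rule = c("strict", "any_later"),
                            ttest = c("welch", "pooled"), map = NULL) {
  retained_rule <- match.arg(retained_rule)
  ttest <- match.arg(ttest)
  map <- map %||% resolve_alters(dataset)
  egos <- dataset$respondents$ego_id
  grp <- stats::setNames(dataset$respondents$group, egos)
  att <- dataset$attendance[dataset$attendance$attended, ]
  att_waves <- lapply(split(att$wave, att$ego_id), sort)
  m <- map$map
  sets_by <- split(m[, c("wave", "alter_id")],
                   list(ego = m$ego_id, kind = m$kind), sep = "\r")
  summaries <- list(); exclusions <- list()
  for (kind in c("confidant", "sexual")) {
    for (ego in egos) {
      waves <- att_waves[[ego]]
      if (is.null(waves) || length(waves) < 2) {
        exclusions[[length(exclusions) + 1L]] <- data.frame(
          ego_id = ego, kind = kind,
          reason = "fewer than two attended visits",
          stringsAsFactors = FALSE)
        next
      }
      sub <- sets_by[[paste(ego, kind, sep = "\r")]]
      sets <- lapply(waves, function(w)
        if (is.null(sub)) character(0)
        else unique(sub$alter_id[sub$wave == w]))
      s <- classify_roster_sets(sets, retained_rule)$summary
      s <- cbind(data.frame(ego_id = ego, kind = kind,
                            stringsAsFactors = FALSE), s)
      if (s$O == 0)
        exclusions[[length(exclusions) + 1L]] <- data.frame(
          ego_id = ego, kind = kind,
          reason = "stability undefined: original network size is zero",
          stringsAsFactors = FALSE)
      s$group <- grp[[ego]]
      summaries[[length(summaries) + 1L]] <- s
    }
  }
  summaries <- if (length(summaries)) do.call(rbind, summaries)
               else data.frame(ego_id = character(0), kind = character(0),
                               O = integer(0), R = integer(0),
                               L = integer(0), N = integer(0),
                               C = integer(0), n_visits = integer(0),
                               stability = numeric(0), turnover = numeric(0),
                               group = character(0), stringsAsFactors = FALSE)
  comparisons <- list()
  for (kind in c("confidant", "sexual")) {
    sk <- summaries[summaries$kind == kind, ]
    for (ratio in c("stability", "turnover")) {
      a <- sk[[ratio]][sk$group == "TGW"]
      b <- sk[[ratio]][sk$group == "MSM"]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      tt <- welch_t_test(a, b, var_equal = (ttest == "pooled"))
      comparisons[[length(comparisons) + 1L]] <- data.frame(
        kind = kind, ratio = ratio,
        mean_tgw = tt$mean_a, mean_msm = tt$mean_b,
        n_tgw = length(a), n_msm = length(b),
        t = tt$t, p = tt$p, flag = tt$flag, stringsAsFactors = FALSE)
    }
  }
  structure(list(summaries = summaries,
                 comparisons = do.call(rbind, comparisons),
                 exclusions = if (length(exclusions))
                   do.call(rbind, exclusions)
                 else data.frame(ego_id = character(0), kind = character(0),
                                 reason = character(0),
                                 stringsAsFactors = FALSE),
                 retained_rule = retained_rule, ttest = ttest),
            class = "netpanel_dynamics")
}
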