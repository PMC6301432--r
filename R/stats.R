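#' Ego-network composition covariates at a wave
#'
#' From each attending ego's resolved, deduplicated roster sets at the
#' given wave, computes the composition covariates used in
#' network-characteristic comparisons: the proportion of transgender
#' confidants, number of transgender confidants who have sex with men,
#' proportion of men confidants, number of men confidants who have sex
#' with men, number of HIV-positive confidants (known positives) and the
#' HIV-positive proportion; and for sexual networks the exchange-sex and
#' payment-received indicators, counts of partners whose stated
#' preference is men / transgender women / cis women, the proportion of
#' partners who exchange sex for pay, and a cis-women-partner indicator.
#' Proportions are taken over alters with a non-missing value of the
#' attribute, with the effective denominator recorded; an ego whose
#' roster is empty (or whose attribute values are all missing) gets count
#' 0 and an undefined (`NA`) proportion.
#'
#' @param dataset a `netpanel_dataset`.
#' @param wave 1-based wave index (default 1).
#' @param map optional precomputed [resolve_alters()] result.
#' @return data frame, one row per ego attending the wave, with `group`
#'   and the covariates plus their `denom_*` effective denominators.
#' @export
ego_composition <- function(dataset, wave = 1L, map = NULL) {
  map <- map %||% resolve_alters(dataset)
  att <- dataset$attendance
  egos <- att$ego_id[att$wave == wave & att$attended]
  egos <- intersect(dataset$respondents$ego_id, egos)
  grp <- stats::setNames(dataset$respondents$group,
                         dataset$respondents$ego_id)
  ros <- merge(dataset$rosters[dataset$rosters$wave == wave, ],
               map$map[, c("nomination_id", "alter_id")],
               by = "nomination_id")
  prop_of <- function(x) {
    d <- sum(!is.na(x))
    list(prop = if (d > 0) sum(x, na.rm = TRUE) / d else NA_real_,
         denom = d)
  }
  rows <- lapply(egos, function(ego) {
    cf <- ros[ros$ego_id == ego & ros$kind == "confidant", ]
    cf <- cf[!duplicated(cf$alter_id), ]
    sx <- ros[ros$ego_id == ego & ros$kind == "sexual", ]
    sx <- sx[!duplicated(sx$alter_id), ]
    tg <- cf$alter_gender == "transgender_woman"
    men <- cf$alter_gender == "man"
    p_tg <- prop_of(tg); p_men <- prop_of(men)
    p_hiv <- prop_of(cf$alter_hiv_positive)
    p_ex <- prop_of(sx$alter_exchange_sex)
    data.frame(
      ego_id = ego, group = unname(grp[ego]), wave = wave,
      n_confidants = nrow(cf), n_partners = nrow(sx),
      prop_tg_confidants = p_tg$prop,
      denom_tg_confidants = p_tg$denom,
      n_tg_confidants_msm = sum(tg & cf$alter_has_sex_with_men,
                                na.rm = TRUE),
      prop_men_confidants = p_men$prop,
      denom_men_confidants = p_men$denom,
      n_men_confidants_msm = sum(men & cf$alter_has_sex_with_men,
                                 na.rm = TRUE),
      n_hiv_pos_confidants = sum(cf$alter_hiv_positive, na.rm = TRUE),
      prop_hiv_pos_confidants = p_hiv$prop,
      denom_hiv_pos_confidants = p_hiv$denom,
      exchange_sex = if (nrow(sx) > 0)
        any(sx$alter_exchange_sex, na.rm = TRUE) else FALSE,
      payment_received = if (nrow(sx) > 0)
        any(sx$alter_payment_received, na.rm = TRUE) else FALSE,
      n_pref_men = sum(sx$alter_partner_preference == "men", na.rm = TRUE),
      n_pref_tgw = sum(sx$alter_partner_preference == "tgw", na.rm = TRUE),
      n_pref_cis_women = sum(sx$alter_partner_preference == "cis_women",
                             na.rm = TRUE),
      prop_partners_exchange = p_ex$prop,
      denom_partners_exchange = p_ex$denom,
      cis_women_partner = if (nrow(sx) > 0)
        any(sx$alter_gender == "cis_woman", na.rm = TRUE) else FALSE,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Dichotomize annual income at $20,000
#'
#' @param amount numeric income (or vector); `NA` stays unknown.
#' @return logical: `TRUE` iff `amount < 20000`. Exactly $20,000 — which
#'   the under/over framing leaves unassigned — is deterministically
#'   classified as not-below.
#' @export
dichotomize_income <- function(amount) {
  stopifnot(is.numeric(amount))
  if (any(amount < 0, na.rm = TRUE))
    stop("income amounts must be nonnegative", call. = FALSE)
  amount < 20000
}

#' Two-sided independent t-test comparison
#'
#' Welch's unequal-variance test by default (Welch-Satterthwaite degrees
#' of freedom); the pooled-variance version by flag. Both samples
#' constant triggers a `"degenerate"` flag instead of an error; fewer
#' than two finite values in either sample is `"not_computable"`.
#'
#' @param values_a,values_b numeric samples (group A is reported first;
#'   `estimate` is `mean_a - mean_b`).
#' @param var_equal use the pooled-variance test.
#' @param conf_level confidence level for the mean-difference CI.
#' @return list of class `netpanel_comparison`: means, `estimate`,
#'   `ci_lo`, `ci_hi`, `t`, `df`, `p`, `n_a`, `n_b`, `test`, `flag`.
#' @export
welch_t_test <- function(values_a, values_b, var_equal = FALSE,
                         conf_level = 0.95) {
  a <- values_a[is.finite(values_a)]
  b <- values_b[is.finite(values_b)]
  res <- list(mean_a = if (length(a)) mean(a) else NA_real_,
              mean_b = if (length(b)) mean(b) else NA_real_,
              estimate = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
              t = NA_real_, df = NA_real_, p = NA_real_,
              n_a = length(a), n_b = length(b),
              test = if (var_equal) "pooled t" else "welch t",
              flag = "ok")
  class(res) <- "netpanel_comparison"
  if (length(a) < 2 || length(b) < 2) {
    res$flag <- "not_computable"
    return(res)
  }
  res$estimate <- res$mean_a - res$mean_b
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    res$flag <- "degenerate"
    return(res)
  }
  tt <- stats::t.test(a, b, var.equal = var_equal,
                      conf.level = conf_level)
  res$t <- unname(tt$statistic)
  res$df <- unname(tt$parameter)
  res$p <- tt$p.value
  res$ci_lo <- tt$conf.int[1]
  res$ci_hi <- tt$conf.int[2]
  res
}

haldane_or <- function(a, b, c, d, conf_level = 0.95) {
  # 2x2 cross-product OR with Haldane-Anscombe 0.5 correction
  a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(or = or, ci_lo = or * exp(-z * se), ci_hi = or * exp(z * se),
       p = 2 * stats::pnorm(-abs(log(or) / se)))
}

#' Unadjusted odds ratio relating a covariate to group membership
#'
#' For a binary ego-level covariate the default framing is
#' outcome-on-group: a logistic model of the covariate on a TGW indicator
#' (MSM the reference group), so the OR is the TGW-vs-MSM odds ratio of
#' the outcome. For a count or proportion covariate the default is
#' group-on-covariate: a logistic model of TGW membership on the
#' covariate, so the OR is per unit of the covariate. Fits are by
#' maximum likelihood (`stats::glm`, `epsilon = 1e-10`) with Wald 95\%
#' CIs and two-sided p-values. Complete separation in the binary case (a
#' zero cell in the 2x2 table) falls back to the cross-product OR with
#' the Haldane-Anscombe 0.5 correction and is flagged.
#'
#' @param data data frame containing `group` (`TGW`/`MSM`) and the
#'   covariate; rows with a missing covariate are dropped
#'   (pairwise-complete denominators).
#' @param covariate covariate column name.
#' @param direction `"auto"`, `"outcome_on_group"` or
#'   `"group_on_covariate"`.
#' @param conf_level confidence level.
#' @return list of class `netpanel_comparison`: `label`, `or`, `ci_lo`,
#'   `ci_hi`, `p`, `direction`, `method` (`"logistic"` or `"haldane"`),
#'   `n_tgw`, `n_msm`, `flag`.
#' @export
unadjusted_or <- function(data, covariate,
                          direction = c("auto", "outcome_on_group",
                                        "group_on_covariate"),
                          conf_level = 0.95) {
  direction <- match.arg(direction)
  x <- data[[covariate]]
  keep <- !is.na(x) & data$group %in% c("TGW", "MSM")
  x <- as.numeric(x[keep])
  g <- as.integer(data$group[keep] == "TGW")
  binary <- is_binary01(x)
  if (direction == "auto")
    direction <- if (binary) "outcome_on_group" else "group_on_covariate"
  res <- list(label = covariate, or = NA_real_, ci_lo = NA_real_,
              ci_hi = NA_real_, p = NA_real_, direction = direction,
              method = "logistic", n_tgw = sum(g == 1),
              n_msm = sum(g == 0), flag = "ok")
  class(res) <- "netpanel_comparison"
  if (length(unique(g)) < 2 || length(x) < 2 || stats::var(x) == 0) {
    if (length(x) >= 2 && stats::var(x) == 0) {
      # covariate constant across both groups: no association
      res$or <- 1; res$p <- 1; res$flag <- "degenerate"
    } else res$flag <- "not_computable"
    return(res)
  }
  if (binary && direction == "outcome_on_group") {
    tab <- table(factor(g, levels = c(1, 0)),
                 factor(x, levels = c(1, 0)))
    if (any(tab == 0)) {
      h <- haldane_or(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2],
                      conf_level)
      res$or <- h$or; res$ci_lo <- h$ci_lo; res$ci_hi <- h$ci_hi
      res$p <- h$p; res$method <- "haldane"; res$flag <- "separation"
      return(res)
    }
  }
  fml <- if (direction == "outcome_on_group") x ~ g else g ~ x
  fit <- suppressWarnings(stats::glm(
    fml, family = stats::binomial(),
    data = data.frame(x = x, g = g),
    control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  co <- summary(fit)$coefficients
  beta <- co[2, 1]; se <- co[2, 2]
  if (!fit$converged || se > 100) {
    # separation without an exact zero cell (possible for count covariates)
    res$flag <- "separation"
    if (binary) {
      tab <- table(factor(g, levels = c(1, 0)), factor(x, levels = c(1, 0)))
      h <- haldane_or(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2], conf_level)
      res$or <- h$or; res$ci_lo <- h$ci_lo; res$ci_hi <- h$ci_hi
      res$p <- h$p; res$method <- "haldane"
    }
    return(res)
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  res$or <- exp(beta)
  res$ci_lo <- exp(beta - z * se)
  res$ci_hi <- exp(beta + z * se)
  res$p <- co[2, 4]
  res
}

#' Network-characteristic odds-ratio table
#'
#' Runs [unadjusted_or()] over the standard ego-composition covariates
#' (confidant composition first, then sexual-network covariates),
#' TGW vs MSM with MSM as the reference group.
#'
#' @param composition an [ego_composition()] table.
#' @param direction passed to [unadjusted_or()].
#' @return data frame, one row per covariate.
#' @export
or_table <- function(composition, direction = "auto") {
  covs <- c("prop_tg_confidants", "n_tg_confidants_msm",
            "prop_men_confidants", "n_men_confidants_msm",
            "n_hiv_pos_confidants",
            "exchange_sex", "payment_received", "n_pref_tgw",
            "n_pref_cis_women", "prop_partners_exchange",
            "cis_women_partner", "n_pref_men")
  rows <- lapply(covs, function(cv) {
    r <- unadjusted_or(composition, cv, direction = direction)
    data.frame(covariate = cv, or = r$or, ci_lo = r$ci_lo,
               ci_hi = r$ci_hi, p = r$p, direction = r$direction,
               method = r$method, n_tgw = r$n_tgw, n_msm = r$n_msm,
               flag = r$flag, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

fmt_pct <- function(num, den) {
  ifelse(den > 0, sprintf("%.1f", 100 * num / den), "")
}

#' Baseline characteristics table with group comparisons
#'
#' Per-group summaries of the respondent covariates: counts and
#' percentages over non-missing (pairwise-complete) denominators for
#' categorical variables, mean (SD) for continuous ones. Comparisons are
#' two-sided: t-test for continuous variables; chi-square for categorical
#' ones, with Fisher's exact test when any expected cell is below 5.
#' Significance is marked at p <= 0.05.
#'
#' @param dataset a `netpanel_dataset` (or a bare respondents data frame).
#' @return list of class `netpanel_baseline`: `table` (one row per
#'   variable/level with formatted cells, p, test, significance),
#'   `group_counts` and `group_share_pct` (each group's share of the
#'   sample, one decimal).
#' @export
baseline_table <- function(dataset) {
  resp <- if (inherits(dataset, "netpanel_dataset")) dataset$respondents
          else dataset
  g <- factor(resp$group, levels = c("TGW", "MSM"))
  n <- nrow(resp)
  counts <- table(g)
  share <- round(100 * as.numeric(counts) / n, 1)
  names(share) <- names(counts)

  continuous <- intersect(c("age_years", "n_partners_6mo"), names(resp))
  binary <- intersect(c("insured", "hiv_positive", "in_relationship",
                        "employed", "income_lt_20k", "stably_housed",
                        "ever_jail"), names(resp))
  categorical <- intersect(c("orientation_w1"), names(resp))
  rows <- list()
  add <- function(df) rows[[length(rows) + 1L]] <<- df

  cat_test <- function(x) {
    tab <- table(g, x)
    if (min(dim(tab)) < 2 || any(rowSums(tab) == 0))
      return(list(p = NA_real_, test = "not_computable"))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5))
      list(p = stats::fisher.test(tab, simulate.p.value = nrow(tab) *
                                    ncol(tab) > 10)$p.value,
           test = "fisher")
    else list(p = stats::chisq.test(tab, correct = FALSE)$p.value,
              test = "chi-square")
  }

  for (v in continuous) {
    x <- resp[[v]]
    a <- x[g == "TGW" & !is.na(x)]; b <- x[g == "MSM" & !is.na(x)]
    tt <- welch_t_test(a, b)
    add(data.frame(
      variable = v, level = "",
      tgw = if (length(a)) sprintf("%.1f (%.1f)", mean(a), stats::sd(a))
            else "",
      msm = if (length(b)) sprintf("%.1f (%.1f)", mean(b), stats::sd(b))
            else "",
      n_tgw = length(a), n_msm = length(b),
      num_tgw = NA_real_, num_msm = NA_real_,
      p = tt$p, test = if (tt$flag == "ok") tt$test else tt$flag,
      significant = !is.na(tt$p) & tt$p <= 0.05,
      stringsAsFactors = FALSE))
  }
  for (v in binary) {
    x <- resp[[v]]
    na_t <- sum(g == "TGW" & !is.na(x)); na_m <- sum(g == "MSM" & !is.na(x))
    k_t <- sum(x[g == "TGW"], na.rm = TRUE)
    k_m <- sum(x[g == "MSM"], na.rm = TRUE)
    ct <- cat_test(x)
    add(data.frame(
      variable = v, level = "",
      tgw = sprintf("%d (%s)", k_t, fmt_pct(k_t, na_t)),
      msm = sprintf("%d (%s)", k_m, fmt_pct(k_m, na_m)),
      n_tgw = na_t, n_msm = na_m, num_tgw = k_t, num_msm = k_m,
      p = ct$p, test = ct$test,
      significant = !is.na(ct$p) & ct$p <= 0.05,
      stringsAsFactors = FALSE))
  }
  for (v in categorical) {
    x <- resp[[v]]
    ct <- cat_test(x)
    lev <- sort(unique(x[!is.na(x)]))
    na_t <- sum(g == "TGW" & !is.na(x)); na_m <- sum(g == "MSM" & !is.na(x))
    add(data.frame(
      variable = v, level = "", tgw = "", msm = "",
      n_tgw = na_t, n_msm = na_m, num_tgw = NA_real_, num_msm = NA_real_,
      p = ct$p, test = ct$test,
      significant = !is.na(ct$p) & ct$p <= 0.05, stringsAsFactors = FALSE))
    for (l in lev) {
      k_t <- sum(x[g == "TGW"] == l, na.rm = TRUE)
      k_m <- sum(x[g == "MSM"] == l, na.rm = TRUE)
      add(data.frame(
        variable = v, level = l,
        tgw = sprintf("%d (%s)", k_t, fmt_pct(k_t, na_t)),
        msm = sprintf("%d (%s)", k_m, fmt_pct(k_m, na_m)),
        n_tgw = na_t, n_msm = na_m, num_tgw = k_t, num_msm = k_m,
        p = NA_real_, test = "", significant = FALSE,
        stringsAsFactors = FALSE))
    }
  }
  structure(list(table = do.call(rbind, rows),
                 group_counts = stats::setNames(as.numeric(counts),
                                                names(counts)),
                 group_share_pct = share),
            class = "netpanel_baseline")
}
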