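make_roster_row <- function(ego, wave, kind, pos, gender = "man",
                            hsm = TRUE, hiv = NA, ex = NA, pay = NA,
                            pref = "men") {
  data.frame(ego_id = ego, wave = wave, kind = kind,
             nomination_id = sprintf("%s.w%d.%s%d", ego, wave,
                                     substr(kind, 1, 1), pos),
             position = pos, is_primary_partner = FALSE,
             alter_gender = gender, alter_has_sex_with_men = hsm,
             alter_hiv_positive = hiv, alter_exchange_sex = ex,
             alter_payment_received = pay, alter_partner_preference = pref,
             stringsAsFactors = FALSE)
}

one_ego_dataset <- function(rosters) {
  resp <- data.frame(ego_id = "E1", group = "TGW", age_years = 22,
                     hiv_positive = NA, employed = NA, income_lt_20k = NA,
                     stably_housed = NA, ever_jail = NA, insured = NA,
                     in_relationship = NA, stringsAsFactors = FALSE)
  att <- data.frame(ego_id = "E1", wave = 1L, attended = TRUE,
                    stringsAsFactors = FALSE)
  m <- data.frame(ego_id = character(0), kind = character(0),
                  nomination_id_earlier = character(0),
                  nomination_id_later = character(0),
                  wave_earlier = integer(0), wave_later = integer(0),
                  stringsAsFactors = FALSE)
  validate_dataset(resp, rosters, m, att)
}

test_that("composition covariates follow the roster fractions", {
  ros <- do.call(rbind, lapply(1:5, function(i)
    make_roster_row("E1", 1L, "confidant", i,
                    gender = if (i <= 2) "transgender_woman" else "man",
                    hiv = c(TRUE, FALSE, NA, NA, NA)[i])))
  comp <- ego_composition(one_ego_dataset(ros), wave = 1)
  expect_equal(comp$prop_tg_confidants, 0.4)
  expect_equal(comp$n_tg_confidants_msm, 2)
  expect_equal(comp$prop_men_confidants, 0.6)
  expect_equal(comp$n_hiv_pos_confidants, 1)
  expect_equal(comp$prop_hiv_pos_confidants, 0.5)  # over the 2 known
  expect_identical(comp$denom_hiv_pos_confidants, 2L)
})

test_that("all-missing alter attributes yield zero counts and undefined proportions", {
  ros <- do.call(rbind, lapply(1:3, function(i)
    make_roster_row("E1", 1L, "confidant", i, hiv = NA)))
  comp <- ego_composition(one_ego_dataset(ros), wave = 1)
  expect_identical(comp$n_hiv_pos_confidants, 0L)
  expect_true(is.na(comp$prop_hiv_pos_confidants))
  expect_identical(comp$denom_hiv_pos_confidants, 0L)
  # empty sexual roster: counts 0, indicators FALSE, proportions NA
  expect_identical(comp$n_partners, 0L)
  expect_false(comp$exchange_sex)
  expect_true(is.na(comp$prop_partners_exchange))
})

test_that("composition equals a ground-truth recomputation on simulated data", {
  sim <- simulate_cohort(small_sim_config(rng_seed = 61))
  ds <- validate_dataset(sim)
  comp <- ego_composition(ds, wave = 1)
  # oracle: recompute transgender-confidant proportions from the raw
  # roster rows (wave 1 nominations are all distinct alters)
  ros <- sim$rosters[sim$rosters$wave == 1 & sim$rosters$kind == "confidant", ]
  byego <- split(ros$alter_gender, ros$ego_id)
  for (ego in names(byego)[1:50]) {
    expect_equal(comp$prop_tg_confidants[comp$ego_id == ego],
                 mean(byego[[ego]] == "transgender_woman"))
  }
})

test_that("income dichotomizes strictly below $20,000", {
  expect_true(dichotomize_income(19999))
  expect_false(dichotomize_income(20000))
  expect_false(dichotomize_income(35000))
  expect_identical(dichotomize_income(NA_real_), NA)
  expect_identical(dichotomize_income(c(0, 19999.99, 20000, NA)),
                   c(TRUE, TRUE, FALSE, NA))
  expect_error(dichotomize_income(-5), "nonnegative")
})

test_that("welch test matches the closed-form oracle and is symmetric", {
  a <- c(1, 2, 3); b <- c(1, 2, 3, 4, 5, 6)
  got <- welch_t_test(a, b)
  want <- welch_oracle(a, b)
  expect_lt(abs(got$t - want$t), 1e-6)
  expect_lt(abs(got$df - want$df), 1e-6)
  expect_lt(abs(got$p - want$p), 1e-6)
  rev <- welch_t_test(b, a)
  expect_equal(rev$p, got$p)
  expect_equal(rev$t, -got$t)
  # identical samples: t = 0, p = 1
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # both samples constant: flagged, not an error
  deg <- welch_t_test(c(2, 2, 2), c(2, 2, 2))
  expect_identical(deg$flag, "degenerate")
  expect_identical(welch_t_test(1, c(1, 2))$flag, "not_computable")
})

test_that("welch test holds its type-I error under the null", {
  set.seed(101)
  rej <- mean(replicate(1000, {
    welch_t_test(rnorm(20), rnorm(25))$p <= 0.05
  }))
  se <- sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(rej - 0.05), 3 * se)
})

test_that("logistic OR equals the cross-product on 2x2 data", {
  # a=10, b=10, c=5, d=20 -> OR = (10*20)/(10*5) = 4
  df <- data.frame(
    group = rep(c("TGW", "MSM"), c(20, 25)),
    y = c(rep(c(TRUE, FALSE), c(10, 10)), rep(c(TRUE, FALSE), c(5, 20))))
  r <- unadjusted_or(df, "y")
  expect_identical(r$method, "logistic")
  expect_lt(abs(r$or - 4), 1e-6)
  expect_identical(r$direction, "outcome_on_group")
  expect_true(r$ci_lo <= r$or && r$or <= r$ci_hi)
  # reciprocal symmetry: OR of the complement is 1/OR
  df$ny <- !df$y
  r2 <- unadjusted_or(df, "ny")
  expect_lt(abs(r2$or - 1 / r$or), 1e-9)
  # identical covariate in both groups: OR 1, p ~ 1
  df$z <- rep(c(TRUE, FALSE), length.out = nrow(df))
  r3 <- unadjusted_or(df, "z")
  expect_lt(abs(r3$or - 1), 0.2)
  expect_gt(r3$p, 0.5)
  df$const <- TRUE
  r4 <- unadjusted_or(df, "const")
  expect_identical(r4$flag, "degenerate")
  expect_identical(r4$or, 1)
})

test_that("random 2x2 tables: logistic equals cross-product to 1e-6; zero cells engage Haldane", {
  set.seed(55)
  n_zero <- 0
  for (rep in 1:40) {
    tab <- matrix(rpois(4, 8), 2)
    df <- data.frame(
      group = rep(c("TGW", "MSM"), c(sum(tab[1, ]), sum(tab[2, ]))),
      y = c(rep(c(TRUE, FALSE), tab[1, ]), rep(c(TRUE, FALSE), tab[2, ])))
    r <- unadjusted_or(df, "y")
    if (any(tab == 0)) {
      n_zero <- n_zero + 1
      expect_identical(r$flag, "separation")
      expect_identical(r$method, "haldane")
      ref <- ((tab[1, 1] + 0.5) * (tab[2, 2] + 0.5)) /
        ((tab[1, 2] + 0.5) * (tab[2, 1] + 0.5))
      expect_lt(abs(r$or - ref), 1e-9)
    } else {
      cross <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
      expect_identical(r$method, "logistic")
      expect_lt(abs(r$or - cross), 1e-6)
    }
  }
})

test_that("count covariates use the group-on-covariate framing", {
  set.seed(9)
  df <- data.frame(group = rep(c("TGW", "MSM"), each = 60),
                   k = c(rpois(60, 3), rpois(60, 1.5)))
  r <- unadjusted_or(df, "k")
  expect_identical(r$direction, "group_on_covariate")
  expect_gt(r$or, 1)  # higher counts predict TGW membership
  expect_lt(r$p, 0.05)
  fit <- glm(I(group == "TGW") ~ k, data = df, family = binomial())
  expect_lt(abs(r$or - exp(coef(fit)[2])), 1e-6)
})

test_that("baseline table reproduces printed shares and self-consistent cells", {
  resp <- data.frame(
    ego_id = sprintf("E%03d", 1:618),
    group = rep(c("TGW", "MSM"), c(47, 571)),
    age_years = rnorm(618, 22.5, 3),
    hiv_positive = runif(618) < 0.4,
    employed = runif(618) < 0.65, income_lt_20k = runif(618) < 0.82,
    stably_housed = runif(618) < 0.75, ever_jail = runif(618) < 0.45,
    insured = runif(618) < 0.55, in_relationship = runif(618) < 0.4,
    stringsAsFactors = FALSE)
  resp$hiv_positive[sample(618, 40)] <- NA
  bl <- baseline_table(resp)
  expect_identical(unname(bl$group_counts["TGW"]), 47)
  expect_identical(unname(bl$group_share_pct["TGW"]), 7.6)
  expect_identical(unname(bl$group_share_pct["MSM"]), 92.4)
  # every percentage cell recomputes from its numerator/denominator
  tb <- bl$table
  for (r in which(!is.na(tb$num_tgw))) {
    shown <- sub("^\\d+ \\(([0-9.]*)\\)$", "\\1", tb$tgw[r])
    expect_identical(shown, sprintf("%.1f", 100 * tb$num_tgw[r] /
                                      tb$n_tgw[r]))
  }
  # missing values shrink the denominators (pairwise-complete)
  expect_lt(tb$n_tgw[tb$variable == "hiv_positive"] +
            tb$n_msm[tb$variable == "hiv_positive"], 618)
})

test_that("an empty group yields summaries with non-computable comparisons", {
  resp <- data.frame(
    ego_id = sprintf("E%02d", 1:10), group = "MSM",
    age_years = rnorm(10, 23, 2), hiv_positive = runif(10) < 0.4,
    employed = TRUE, income_lt_20k = FALSE, stably_housed = TRUE,
    ever_jail = FALSE, insured = TRUE, in_relationship = FALSE,
    stringsAsFactors = FALSE)
  bl <- baseline_table(resp)
  expect_identical(unname(bl$group_counts["TGW"]), 0)
  expect_true(all(is.na(bl$table$p)))
})
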