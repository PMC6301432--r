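#' Generate a synthetic hidden population with initial tie structures
#'
#' Draws group labels (TGW with probability `prop_tgw`, otherwise MSM),
#' baseline covariates at their per-group prevalences, and initial
#' undirected confidant and sexual tie sets from a two-block
#' degree-homogeneous random-graph model: the edge probability between
#' members of groups g and h is proportional to `mixing[g, h]`, scaled so
#' that the expected mean degree equals the configured mean degree. An
#' external pool of cis-women partners (sexual ties only, attached at the
#' sample stage) is generated alongside.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `netpanel_population`: a list with `members`
#'   (one row per hidden-population or external-pool member, with group,
#'   gender, covariates and alter attributes) and `ties` (per-kind
#'   undirected edge lists over hidden-population member ids).
#' @export
generate_population <- function(config) {
  config <- validate_sim_config(config)
  set_stream_seed(config$rng_seed, "population")
  n <- config$population_size
  group <- c("MSM", "TGW")[(stats::runif(n) < config$prop_tgw) + 1L]
  ids <- sprintf("P%05d", seq_len(n))

  age_mean <- c(TGW = 22.1, MSM = 22.8)
  age_sd <- c(TGW = 2.6, MSM = 3.2)
  age <- pmin(29, pmax(16, stats::rnorm(n, age_mean[group], age_sd[group])))

  draw_cov <- function(name) {
    p <- vapply(group, function(g) config$covariate_prevalences[[g]][[name]],
                numeric(1))
    x <- stats::runif(n) < p
    x[stats::runif(n) < config$covariate_missingness] <- NA
    x
  }
  cov_names <- c("hiv_positive", "employed", "income_lt_20k",
                 "stably_housed", "ever_jail", "insured", "in_relationship")
  covs <- lapply(cov_names, draw_cov)
  names(covs) <- cov_names

  # sexual orientation per wave: Wave-1 draw from the per-group
  # distribution, later waves keep the same identity with the per-group
  # stability probability, else redraw
  ori_dist <- list(
    TGW = c(gay = 0.438, straight = 0.333, bisexual = 0.167, other = 0.063),
    MSM = c(gay = 0.684, straight = 0.011, bisexual = 0.279, other = 0.027))
  ori_dist <- lapply(ori_dist, function(d) d / sum(d))
  ori_stable <- c(TGW = 0.688, MSM = 0.836)
  draw_ori <- function(g) sample(names(ori_dist[[g]]), 1,
                                 prob = ori_dist[[g]])
  orientation <- matrix(NA_character_, n, config$n_waves)
  orientation[, 1] <- vapply(group, draw_ori, character(1))
  if (config$n_waves > 1) {
    for (w in 2:config$n_waves) {
      keep <- stats::runif(n) < ori_stable[group]
      orientation[, w] <- ifelse(keep, orientation[, w - 1],
                                 vapply(group, draw_ori, character(1)))
    }
  }

  # self-reported partner count over the recall window (survey item, not
  # roster-derived): negative binomial matched to group mean/SD
  nb <- list(TGW = c(mu = 7.6, size = 7.6^2 / (15.2^2 - 7.6)),
             MSM = c(mu = 4.0, size = 4.0^2 / (4.9^2 - 4.0)))
  n_partners <- vapply(group, function(g)
    stats::rnbinom(1, mu = nb[[g]]["mu"], size = nb[[g]]["size"]),
    numeric(1))

  pref <- vapply(group, function(g)
    sample(names(config$alter_attr$pref_dist[[g]]), 1,
           prob = config$alter_attr$pref_dist[[g]]), character(1))

  members <- data.frame(
    member_id = ids, stratum = "population", group = group,
    gender = ifelse(group == "TGW", "transgender_woman", "man"),
    has_sex_with_men = TRUE,
    age_years = round(age, 1),
    orientation = I(orientation),
    n_partners_6mo = as.integer(n_partners),
    partner_preference = pref,
    stringsAsFactors = FALSE)
  for (nm in cov_names) members[[nm]] <- covs[[nm]]

  n_ext <- round(config$external_pool_frac * n)
  if (n_ext > 0) {
    ext_hiv <- stats::runif(n_ext) < 0.05
    ext <- data.frame(
      member_id = sprintf("X%05d", seq_len(n_ext)), stratum = "external",
      group = NA_character_, gender = "cis_woman", has_sex_with_men = TRUE,
      age_years = round(pmin(45, pmax(16, stats::rnorm(n_ext, 24, 4))), 1),
      orientation = I(matrix(NA_character_, n_ext, config$n_waves)),
      n_partners_6mo = NA_integer_,
      partner_preference = "men",
      stringsAsFactors = FALSE)
    for (nm in cov_names) ext[[nm]] <- NA
    ext$hiv_positive <- ext_hiv
    members <- rbind(members, ext)
  }

  ties <- list(
    confidant = sample_block_edges(ids, group, config$mixing,
                                   config$mean_confidant_degree),
    sexual = sample_block_edges(ids, group, config$mixing,
                                config$mean_sexual_degree))

  structure(list(members = members, ties = ties, config = config),
            class = "netpanel_population")
}

# Two-block degree-homogeneous random graph. Block edge probabilities are
# p[g,h] = s_g * s_h * mixing[g,h], with the per-group scales s_g solved
# (fixed-point iteration) so that every group's expected degree equals
# `mean_degree` regardless of the group-size imbalance; `mixing` sets the
# relative within/between-group tie odds (homophily).
sample_block_edges <- function(ids, group, mixing, mean_degree) {
  empty <- data.frame(i = character(0), j = character(0),
                      stringsAsFactors = FALSE)
  if (mean_degree <= 0) return(empty)
  idx <- split(ids, factor(group, levels = c("TGW", "MSM")))
  ng <- lengths(idx)
  present <- names(ng)[ng > 0]
  s <- stats::setNames(rep(0.01, 2), c("TGW", "MSM"))
  for (it in seq_len(200)) {
    for (g in present) {
      denom <- sum(vapply(present, function(h)
        s[[h]] * mixing[g, h] * (ng[[h]] - (g == h)), numeric(1)))
      s[[g]] <- if (denom > 0) mean_degree / denom else 0
    }
  }
  blocks <- list(c("TGW", "TGW"), c("TGW", "MSM"), c("MSM", "MSM"))
  M <- vapply(blocks, function(b) {
    na <- ng[[b[1]]]; nb <- ng[[b[2]]]
    if (b[1] == b[2]) na * (na - 1) / 2 else na * nb
  }, numeric(1))
  out <- empty
  for (k in seq_along(blocks)) {
    if (M[k] == 0) next
    b <- blocks[[k]]
    p <- min(1, s[[b[1]]] * s[[b[2]]] * mixing[b[1], b[2]])
    ne <- stats::rbinom(1, M[k], p)
    if (ne == 0) next
    prs <- if (b[1] == b[2]) sample_distinct_pairs(idx[[b[1]]], k = ne)
           else sample_distinct_pairs(idx[[b[1]]], idx[[b[2]]], k = ne)
    out <- rbind(out, prs)
  }
  # canonical order for reproducible downstream iteration
  lo <- pmin(out$i, out$j); hi <- pmax(out$i, out$j)
  out <- data.frame(i = lo, j = hi, stringsAsFactors = FALSE)
  out[order(out$i, out$j), , drop = FALSE]
}

#' Run seeded coupon-based RDS recruitment over the population
#'
#' Seeds are drawn without replacement (by default proportionally to
#' confidant degree, emulating highly socially connected initial
#' participants). Recruitment then proceeds breadth-wise in coupon-issue
#' order: each enrollee passes at most `coupons_per_recruit` coupons to
#' randomly chosen not-yet-enrolled neighbors over the recruitment tie
#' structure, until `target_sample` members are enrolled or chains are
#' exhausted (reported as a warning with the achieved size, not an error).
#'
#' @param population a [generate_population()] result (or a compatible
#'   list with `members` and `ties`).
#' @param config a [sim_config()] object.
#' @return a list of class `netpanel_recruitment`: `sample` (data frame
#'   with `ego_id`, `recruiter_id` — `NA` for seeds — and `wave_of_entry`,
#'   the recruitment generation starting at 0 for seeds) and `achieved`
#'   (enrolled count).
#' @export
run_rds_recruitment <- function(population, config) {
  config <- validate_sim_config(config)
  set_stream_seed(config$rng_seed, "recruitment")
  pop_ids <- population$members$member_id[
    population$members$stratum == "population"]
  edges <- population$ties$confidant
  if (config$recruit_on == "union")
    edges <- unique(rbind(edges, population$ties$sexual))
  nbr <- make_adjacency(pop_ids, edges)

  n_pop <- length(pop_ids)
  k_seeds <- min(config$n_seeds, n_pop)
  deg <- lengths(nbr)[pop_ids]
  if (config$seed_selection == "degree" && any(deg > 0)) {
    n_pos <- sum(deg > 0)
    if (n_pos >= k_seeds) {
      seeds <- sample(pop_ids, k_seeds, prob = deg)
    } else {
      seeds <- c(sample(pop_ids[deg > 0], n_pos, prob = deg[deg > 0]),
                 sample(pop_ids[deg == 0], k_seeds - n_pos))
    }
  } else {
    seeds <- sample(pop_ids, k_seeds)
  }

  target <- min(config$target_sample, n_pop)
  enrolled <- structure(rep(FALSE, n_pop), names = pop_ids)
  enrolled[seeds] <- TRUE
  order_ids <- seeds
  recruiter <- rep(NA_character_, length(seeds))
  depth <- rep(0L, length(seeds))
  i <- 1L
  while (length(order_ids) < target && i <= length(order_ids)) {
    ego <- order_ids[i]
    cand <- nbr[[ego]]
    cand <- cand[!enrolled[cand]]
    if (length(cand) > 0 && config$coupons_per_recruit > 0) {
      take <- min(config$coupons_per_recruit, length(cand),
                  target - length(order_ids))
      picked <- if (length(cand) == 1) cand else sample(cand, take)
      picked <- picked[seq_len(take)]
      enrolled[picked] <- TRUE
      order_ids <- c(order_ids, picked)
      recruiter <- c(recruiter, rep(ego, take))
      depth <- c(depth, rep(depth[i] + 1L, take))
    }
    i <- i + 1L
  }
  if (length(order_ids) < config$target_sample)
    warning(sprintf(
      "RDS recruitment exhausted at %d of %d targeted enrollees",
      length(order_ids), config$target_sample), call. = FALSE)
  structure(list(
    sample = data.frame(ego_id = order_ids, recruiter_id = recruiter,
                        wave_of_entry = depth, stringsAsFactors = FALSE),
    achieved = length(order_ids)),
    class = "netpanel_recruitment")
}

make_adjacency <- function(ids, edges) {
  nbr <- stats::setNames(vector("list", length(ids)), ids)
  nbr[] <- list(character(0))
  if (nrow(edges) > 0) {
    all_from <- c(edges$i, edges$j)
    all_to <- c(edges$j, edges$i)
    keep <- all_from %in% ids & all_to %in% ids
    sp <- split(all_to[keep], all_from[keep])
    nbr[names(sp)] <- sp
  }
  nbr
}
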