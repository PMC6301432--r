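# Independent brute-force oracles used across the suite. These never call
# package internals or igraph: distances via Floyd-Warshall, betweenness
# via exhaustive geodesic enumeration, Welch's test from the closed form.

oracle_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[adj == 1] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# all geodesics from s to t, as lists of vertex indices
oracle_geodesics <- function(adj, D, s, t) {
  if (!is.finite(D[s, t]) || s == t) return(list())
  if (D[s, t] == 1) return(list(c(s, t)))
  out <- list()
  for (u in which(adj[s, ] == 1)) {
    if (D[u, t] == D[s, t] - 1) {
      for (p in if (u == t) list(t) else oracle_geodesics(adj, D, u, t))
        out[[length(out) + 1L]] <- c(s, p)
    }
  }
  out
}

oracle_metrics <- function(adj) {
  n <- nrow(adj)
  D <- oracle_distances(adj)
  deg <- rowSums(adj)
  btw <- numeric(n)
  if (n >= 3) {
    for (s in 1:(n - 1)) for (t in (s + 1):n) {
      paths <- oracle_geodesics(adj, D, s, t)
      if (length(paths) == 0) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        on_path <- sum(vapply(paths, function(p) v %in% p, logical(1)))
        btw[v] <- btw[v] + on_path / length(paths)
      }
    }
    btw <- btw / ((n - 1) * (n - 2) / 2)
  }
  Doff <- D
  diag(Doff) <- Inf
  reach <- rowSums(is.finite(Doff))
  sumd <- apply(Doff, 1, function(d) sum(d[is.finite(d)]))
  clo <- ifelse(reach > 0 & n > 1, (reach / (n - 1)) * (reach / sumd), 0)
  aspl <- ifelse(reach > 0, sumd / reach, NA_real_)
  list(degree = deg, betweenness = btw, closeness = clo, aspl = aspl)
}

random_adjacency <- function(n, p = 0.4) {
  adj <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (stats::runif(1) < p) adj[i, j] <- adj[j, i] <- 1
  adj
}

graph_from_adjacency_names <- function(adj) {
  # build an igraph with named vertices v1..vn from a 0/1 matrix
  n <- nrow(adj)
  nm <- paste0("v", seq_len(n))
  el <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  edf <- data.frame(from = nm[el[, 1]], to = nm[el[, 2]],
                    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edf, directed = FALSE,
                                vertices = data.frame(name = nm))
}

welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# minimal hand-built dataset: per-ego rosters given as alter *labels*;
# match records are generated from shared labels across waves, the same
# way a respondent confirming "same person as last time" would produce
# them. Labels never leak into nomination ids.
build_panel <- function(rosters_by_ego, kind = "confidant",
                        groups = NULL, n_waves = NULL) {
  egos <- names(rosters_by_ego)
  if (is.null(n_waves))
    n_waves <- max(unlist(lapply(rosters_by_ego, function(x)
      as.integer(sub("^w", "", names(x))))))
  resp <- data.frame(
    ego_id = egos,
    group = if (is.null(groups)) rep("MSM", length(egos))
            else unname(groups[egos]),
    age_years = 22, hiv_positive = NA, employed = NA, income_lt_20k = NA,
    stably_housed = NA, ever_jail = NA, insured = NA, in_relationship = NA,
    stringsAsFactors = FALSE)
  ros <- list(); att <- list(); mat <- list()
  for (ego in egos) {
    waves_here <- as.integer(sub("^w", "", names(rosters_by_ego[[ego]])))
    for (w in seq_len(n_waves))
      att[[length(att) + 1L]] <- data.frame(
        ego_id = ego, wave = w, attended = w %in% waves_here,
        stringsAsFactors = FALSE)
    seen <- list()  # label -> earlier nominations
    for (wi in seq_along(waves_here)) {
      w <- waves_here[wi]
      labels <- rosters_by_ego[[ego]][[paste0("w", w)]]
      if (length(labels) == 0) next
      nom <- sprintf("%s.w%d.%s%d", ego, w, substr(kind, 1, 1),
                     seq_along(labels))
      ros[[length(ros) + 1L]] <- data.frame(
        ego_id = ego, wave = w, kind = kind, nomination_id = nom,
        position = seq_along(labels), is_primary_partner = FALSE,
        alter_gender = "man", alter_has_sex_with_men = TRUE,
        alter_hiv_positive = NA, alter_exchange_sex = NA,
        alter_payment_received = NA, alter_partner_preference = "men",
        stringsAsFactors = FALSE)
      for (li in seq_along(labels)) {
        lb <- labels[li]
        for (prev in seen[[lb]])
          mat[[length(mat) + 1L]] <- data.frame(
            ego_id = ego, kind = kind,
            nomination_id_earlier = prev$nom,
            nomination_id_later = nom[li],
            wave_earlier = prev$wave, wave_later = w,
            stringsAsFactors = FALSE)
        seen[[lb]] <- c(seen[[lb]], list(list(nom = nom[li], wave = w)))
      }
    }
  }
  empty_m <- data.frame(ego_id = character(0), kind = character(0),
                        nomination_id_earlier = character(0),
                        nomination_id_later = character(0),
                        wave_earlier = integer(0), wave_later = integer(0),
                        stringsAsFactors = FALSE)
  validate_dataset(resp,
                   do.call(rbind, ros),
                   if (length(mat)) do.call(rbind, mat) else empty_m,
                   do.call(rbind, att))
}

small_sim_config <- function(...) {
  args <- list(...)
  defaults <- list(population_size = 400, n_seeds = 10, target_sample = 150,
                   n_waves = 2, rng_seed = 42)
  do.call(sim_config, utils::modifyList(defaults, args))
}
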