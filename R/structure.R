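#' Assemble the composite sociometric graph
#'
#' Builds one undirected simple graph over enrolled egos and their
#' resolved alters, with typed edges: `rds` (recruiter-recruit pairs from
#' the recruitment chains), `confidant` and `sexual` (ego-alter roster
#' ties). Parallel nominations merge into a single edge whose type set is
#' the union (e.g. the same person named as confidant and sex partner
#' yields one edge typed `confidant,sexual`, using the respondent's
#' overlap confirmations); per-edge wave provenance is kept as a set.
#'
#' Observed name-generator data cannot tell that two different egos named
#' the same real person, so each ego's alters are distinct nodes; with
#' simulator ground truth (`identity`), nominations are linked to true
#' member ids, enrolled alters collapse onto their ego node and shared
#' alters merge.
#'
#' @param dataset a `netpanel_dataset`.
#' @param edge_kinds nonempty subset of `c("rds", "confidant", "sexual")`.
#' @param waves waves whose roster ties to include (default: all).
#' @param identity optional ground-truth identity table
#'   (`nomination_id`, `member_id`) enabling cross-ego alter merging.
#' @param map optional precomputed [resolve_alters()] result.
#' @return an `igraph` object with vertex attributes `name`, `group`,
#'   `enrolled` and edge attributes `types`, `waves` (comma-joined sets).
#' @export
assemble_graph <- function(dataset, edge_kinds = c("rds", "confidant",
                                                   "sexual"),
                           waves = NULL, identity = NULL, map = NULL) {
  stopifnot(length(edge_kinds) > 0,
            all(edge_kinds %in% c("rds", "confidant", "sexual")))
  waves <- waves %||% sort(unique(dataset$attendance$wave))
  resp <- dataset$respondents
  edges <- list()

  if ("rds" %in% edge_kinds) {
    if (!"recruiter_id" %in% names(resp))
      stop("dataset has no recruitment table: rds edges unavailable",
           call. = FALSE)
    rec <- resp[!is.na(resp$recruiter_id), c("ego_id", "recruiter_id")]
    if (nrow(rec) > 0)
      edges[[length(edges) + 1L]] <- data.frame(
        from = rec$recruiter_id, to = rec$ego_id, type = "rds",
        wave = NA_integer_, stringsAsFactors = FALSE)
  }

  roster_kinds <- intersect(edge_kinds, c("confidant", "sexual"))
  alter_nodes <- data.frame(node = character(0), group = character(0),
                            stringsAsFactors = FALSE)
  if (length(roster_kinds) > 0) {
    map <- map %||% resolve_alters(dataset)
    m <- map$map[map$map$kind %in% roster_kinds & map$map$wave %in% waves, ]
    if (!is.null(identity)) {
      node_of <- stats::setNames(identity$member_id, identity$nomination_id)
      m$node <- unname(node_of[m$nomination_id])
    } else {
      # merge confidant/sexual alter ids of the same ego through the
      # respondent's overlap confirmations (canonical: confidant id)
      ov <- map$overlap
      relabel <- stats::setNames(ov$alter_id_confidant, ov$alter_id_sexual)
      m$node <- ifelse(m$alter_id %in% names(relabel),
                       unname(relabel[m$alter_id]), m$alter_id)
    }
    keep <- !is.na(m$node) & m$node != m$ego_id
    m <- m[keep, ]
    if (nrow(m) > 0) {
      edges[[length(edges) + 1L]] <- data.frame(
        from = m$ego_id, to = m$node, type = m$kind, wave = m$wave,
        stringsAsFactors = FALSE)
      extra <- setdiff(unique(m$node), resp$ego_id)
      alter_nodes <- data.frame(node = extra, group = NA_character_,
                                stringsAsFactors = FALSE)
    }
  }

  edf <- if (length(edges)) do.call(rbind, edges)
         else data.frame(from = character(0), to = character(0),
                         type = character(0), wave = integer(0),
                         stringsAsFactors = FALSE)
  if (nrow(edf) > 0) {
    lo <- pmin(edf$from, edf$to); hi <- pmax(edf$from, edf$to)
    key <- paste(lo, hi, sep = "\r")
    types <- vapply(split(edf$type, key), function(x)
      paste(sort(unique(x)), collapse = ","), character(1))
    waves_of <- vapply(split(edf$wave, key), function(x)
      paste(sort(unique(x[!is.na(x)])), collapse = ","), character(1))
    uq <- !duplicated(key)
    edf <- data.frame(from = lo[uq], to = hi[uq],
                      types = unname(types[key[uq]]),
                      waves = unname(waves_of[key[uq]]),
                      stringsAsFactors = FALSE)
  } else {
    edf <- data.frame(from = character(0), to = character(0),
                      types = character(0), waves = character(0),
                      stringsAsFactors = FALSE)
  }
  vdf <- rbind(
    data.frame(node = resp$ego_id, group = resp$group,
               stringsAsFactors = FALSE),
    alter_nodes)
  vdf <- vdf[!duplicated(vdf$node), ]
  vdf$enrolled <- vdf$node %in% resp$ego_id
  names(vdf)[1] <- "name"
  igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
}

#' Per-node structural metrics of the composite graph
#'
#' Degree; betweenness centrality normalized by `(n-1)(n-2)/2` (the
#' number of other-node pairs, so values lie in `[0, 1]`); closeness
#' centrality computed over each node's reachable set and scaled by the
#' component-size correction `(reachable - 1)/(n - 1)`, so that on a
#' connected graph it is the classical closeness and on a disconnected
#' graph a node never scores higher than it would in its component alone;
#' and average shortest path length, the mean geodesic distance to
#' reachable nodes. Isolated nodes get betweenness and closeness 0 and an
#' undefined (`NA`) path length, flagged in the `isolated` column.
#'
#' @param graph an undirected `igraph` graph.
#' @return data frame with columns `node`, `degree`, `betweenness`,
#'   `closeness`, `aspl`, `isolated`.
#' @export
node_metrics <- function(graph) {
  n <- igraph::vcount(graph)
  stopifnot(n > 0)
  deg <- igraph::degree(graph)
  btw_raw <- igraph::betweenness(graph, directed = FALSE)
  pairs <- (n - 1) * (n - 2) / 2
  btw <- if (pairs > 0) btw_raw / pairs else rep(0, n)
  D <- igraph::distances(graph)
  diag(D) <- Inf
  reach <- rowSums(is.finite(D))
  sumd <- apply(D, 1, function(d) sum(d[is.finite(d)]))
  clo <- ifelse(reach > 0 & n > 1,
                (reach / (n - 1)) * (reach / sumd), 0)
  aspl <- ifelse(reach > 0, sumd / reach, NA_real_)
  data.frame(node = igraph::V(graph)$name, degree = as.integer(deg),
             betweenness = unname(btw), closeness = unname(clo),
             aspl = unname(aspl), isolated = unname(reach == 0),
             stringsAsFactors = FALSE)
}

#' Compare structural network metrics between groups
#'
#' Group means of the four node metrics over enrolled egos only (alter
#' nodes carry no group and are excluded), with a two-sided independent
#' t-test per metric.
#'
#' @param metrics a [node_metrics()] data frame.
#' @param respondents the respondents table (for group labels).
#' @param ttest `"welch"` or `"pooled"`.
#' @return data frame: one row per metric with group means, n, t, p and a
#'   flag (`"not_computable"` when a group has fewer than two egos;
#'   `"degenerate"` when both groups are constant).
#' @export
group_structure_comparison <- function(metrics, respondents,
                                       ttest = c("welch", "pooled")) {
  ttest <- match.arg(ttest)
  grp <- stats::setNames(respondents$group, respondents$ego_id)
  mm <- metrics[metrics$node %in% names(grp), ]
  mm$group <- unname(grp[mm$node])
  out <- list()
  for (metric in c("degree", "betweenness", "closeness", "aspl")) {
    a <- mm[[metric]][mm$group == "TGW"]
    b <- mm[[metric]][mm$group == "MSM"]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    tt <- welch_t_test(a, b, var_equal = (ttest == "pooled"))
    out[[length(out) + 1L]] <- data.frame(
      metric = metric, mean_tgw = tt$mean_a, mean_msm = tt$mean_b,
      n_tgw = length(a), n_msm = length(b), t = tt$t, p = tt$p,
      flag = tt$flag, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Export / import the composite graph as GraphML
#'
#' Round-trips node attributes (`group`, `enrolled`) and edge attributes
#' (`types`, `waves`) losslessly.
#'
#' @param graph an `igraph` graph from [assemble_graph()].
#' @param path file path.
#' @return `write_graphml` returns `path` invisibly; `read_graphml`
#'   returns the graph.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if ("id" %in% igraph::vertex_attr_names(g) &&
      !"name" %in% igraph::vertex_attr_names(g))
    igraph::V(g)$name <- igraph::V(g)$id
  if ("group" %in% igraph::vertex_attr_names(g)) {
    grp <- igraph::V(g)$group
    grp[grp == "NA"] <- NA_character_  # GraphML serializes NA as "NA"
    igraph::V(g)$group <- grp
  }
  g
}
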