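# Network products of a rate matrix: time-constant classes, antenna groups
# (connected components under a coupling-reach cutoff), and ranked
# (possibly mediated) transfer routes.

.tau_table <- function(rates) {
  if (inherits(rates, "rate_matrix")) {
    list(tau = rates$tau, ids = rates$ids)
  } else if (inherits(rates, "domain_rate_matrix")) {
    list(tau = rates$tau, ids = rownames(rates$tau))
  } else stop("rates must be a rate_matrix or domain_rate_matrix")
}

#' Classify transfer edges into time-constant bins
#'
#' Half-open binning of time constants: with the default edges `c(1, 10, 20)`
#' ps, classes are FAST (tau < 1 ps), MID (1 <= tau < 10), SLOW
#' (10 <= tau < 20) and OMITTED (tau >= 20 ps, the conventional threshold
#' below which pairs are dropped from transfer maps).
#'
#' @param rates A `rate_matrix` or `domain_rate_matrix`.
#' @param bins Strictly ascending positive bin edges (ps).
#' @return Data frame with `donor`, `acceptor`, `tau_ps`, `class` (factor).
#' @export
classify_edges <- function(rates, bins = c(1, 10, 20)) {
  if (any(bins <= 0) || is.unsorted(bins, strictly = TRUE))
    stop("bins must be strictly ascending and positive")
  tt <- .tau_table(rates)
  nb <- length(bins)
  labels <- if (nb == 3L) c("FAST", "MID", "SLOW", "OMITTED")
            else c(paste0("BIN", seq_len(nb)), "OMITTED")
  idx <- which(row(tt$tau) != col(tt$tau), arr.ind = TRUE)
  tau <- tt$tau[idx]
  cls <- labels[findInterval(tau, bins, left.open = FALSE) + 1L]
  data.frame(donor = tt$ids[idx[, 1]], acceptor = tt$ids[idx[, 2]],
             tau_ps = tau,
             class = factor(cls, levels = labels),
             stringsAsFactors = FALSE)
}

#' Group antenna domains by transfer reach
#'
#' Builds an undirected graph over the antenna domains with an edge wherever
#' the better direction of a pair transfers within `cutoff`
#' (`min(tau_DA, tau_AD) <= cutoff`), and returns its connected components.
#' The core domain is excluded from grouping.
#'
#' @param domain_rates A `domain_rate_matrix`.
#' @param cutoff Time-constant cutoff in ps (> 0; default 20 ps, the map
#'   omission threshold).
#' @param core_id Domain id of the core aggregate, or `NULL` when the network
#'   has no core.
#' @return List of character vectors (one per group, members sorted); groups
#'   ordered by their smallest member id.
#' @export
group_antennae <- function(domain_rates, cutoff = 20, core_id = "CORE") {
  stopifnot(inherits(domain_rates, "domain_rate_matrix"), cutoff > 0)
  ids <- rownames(domain_rates$tau)
  if (!is.null(core_id)) {
    if (!core_id %in% ids) stop("unknown core domain id: ", core_id)
    ids <- setdiff(ids, core_id)
  }
  tau <- domain_rates$tau[ids, ids, drop = FALSE]
  best <- pmin(tau, t(tau))
  adj <- !is.na(best) & best <= cutoff
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  groups <- lapply(split(ids, comp$membership), sort)
  unname(groups[order(vapply(groups, `[`, "", 1L))])
}

#' Enumerate and rank transfer routes between two domains
#'
#' Enumerates all simple paths from `source` to `target` with at most
#' `max_steps` edges over the finite-rate graph and ranks them ascending by
#' the route score: the bottleneck (slowest-step) time constant by default,
#' since pathways are compared by their limiting rate, or the summed step
#' time constants with `score = "total"`. Ties are broken by path length,
#' then lexicographically by the domain-id sequence.
#'
#' @param domain_rates A `domain_rate_matrix`.
#' @param source,target Distinct domain ids.
#' @param max_steps Maximum number of steps (edges) per route, >= 1.
#' @param top_k Number of routes to return (default all).
#' @param score `"bottleneck"` or `"total"`.
#' @return Data frame with `rank`, `route` ("A -> B -> C"), `n_steps`,
#'   `bottleneck_tau_ps`, `total_tau_ps`, and a list column `step_tau_ps`.
#' @export
rank_routes <- function(domain_rates, source, target, max_steps = 2,
                        top_k = Inf, score = c("bottleneck", "total")) {
  score <- match.arg(score)
  stopifnot(inherits(domain_rates, "domain_rate_matrix"), max_steps >= 1)
  ids <- rownames(domain_rates$tau)
  if (!source %in% ids) stop("unknown domain: ", source)
  if (!target %in% ids) stop("unknown domain: ", target)
  if (identical(source, target)) stop("source and target must differ")
  tau <- domain_rates$tau
  adj <- !is.na(tau) & is.finite(tau)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
  paths <- igraph::all_simple_paths(g, from = source, to = target,
                                    mode = "out", cutoff = max_steps)
  if (!length(paths))
    return(data.frame(rank = integer(), route = character(),
                      n_steps = integer(), bottleneck_tau_ps = numeric(),
                      total_tau_ps = numeric()))
  rows <- lapply(paths, function(p) {
    v <- igraph::as_ids(p)
    steps <- vapply(seq_len(length(v) - 1L), function(i)
      tau[v[i], v[i + 1L]], 0)
    list(domains = v, steps = steps,
         bottleneck = max(steps), total = sum(steps))
  })
  key <- vapply(rows, function(r)
    if (score == "bottleneck") r$bottleneck else r$total, 0)
  len <- vapply(rows, function(r) length(r$steps), 0L)
  lex <- vapply(rows, function(r) paste(r$domains, collapse = "\r"), "")
  ord <- order(key, len, lex)
  rows <- rows[ord]
  out <- data.frame(
    rank = seq_along(rows),
    route = vapply(rows, function(r) paste(r$domains, collapse = " -> "), ""),
    n_steps = vapply(rows, function(r) length(r$steps), 0L),
    bottleneck_tau_ps = vapply(rows, `[[`, 0, "bottleneck"),
    total_tau_ps = vapply(rows, `[[`, 0, "total"),
    stringsAsFactors = FALSE)
  out$step_tau_ps <- I(lapply(rows, `[[`, "steps"))
  utils::head(out, n = top_k)
}

#' Export a rate network (CSV + GraphML + JSON summary)
#'
#' Writes the full classified edge list as CSV (including OMITTED edges), a
#' GraphML graph restricted to non-OMITTED edges, and a JSON summary holding
#' the bin edges, grouping cutoff, groups and the constants version. The JSON
#' is byte-deterministic for fixed inputs.
#'
#' @param rates A `rate_matrix` or `domain_rate_matrix`.
#' @param classes Output of [classify_edges()] on `rates`.
#' @param groups Output of [group_antennae()] (or `NULL`).
#' @param dir Output directory (created if needed).
#' @param bins,cutoff Metadata echoed into the summary.
#' @return Named character vector of the written file paths, invisibly.
#' @export
export_network <- function(rates, classes, groups = NULL, dir,
                           bins = c(1, 10, 20), cutoff = 20) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "edges.csv")
  utils::write.csv(classes, csv, row.names = FALSE, quote = FALSE)
  keep <- classes[classes$class != "OMITTED" & is.finite(classes$tau_ps), ]
  g <- igraph::graph_from_data_frame(
    keep[, c("donor", "acceptor")], directed = TRUE,
    vertices = data.frame(name = .tau_table(rates)$ids))
  igraph::E(g)$tau_ps <- keep$tau_ps
  igraph::E(g)$class <- as.character(keep$class)
  gml <- file.path(dir, "network.graphml")
  igraph::write_graph(g, gml, format = "graphml")
  summary <- list(
    n_nodes = igraph::vcount(g),
    n_edges_kept = igraph::ecount(g),
    n_edges_total = nrow(classes),
    bins_ps = bins, group_cutoff_ps = cutoff,
    groups = if (is.null(groups)) list() else unname(groups),
    constants_version = .eet_const$version)
  js <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(edges = csv, graphml = gml, summary = js))
}
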