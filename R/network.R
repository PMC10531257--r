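#' Infer a functional connectivity graph from spike trains
#'
#' For every ordered pair of active electrodes the spike cross-correlogram
#' is binned over lags `(0, max_lag_ms]`; its peak is compared with the
#' null distribution obtained by re-computing the peak after uniformly
#' jittering the target train within `+/- jitter_ms` (`n_surrogates`
#' times).  A directed edge source -> target is drawn when the observed
#' peak exceeds `surrogate mean + z(alpha) * surrogate SD`; the edge weight
#' is the standardized exceedance (z-score) and the edge lag the center of
#' the winning bin.  Jittering preserves firing rates and slow comodulation
#' but destroys millisecond timing, so the test is specific to fine
#' time-locked coupling.
#'
#' @param spikes A [spike_trains()] table.
#' @param bin_ms Correlogram bin width, ms (default 5).
#' @param max_lag_ms Largest lag considered, ms (default 150).
#' @param n_surrogates Number of jitter surrogates (>= 19; default 20).
#' @param alpha Per-pair significance level (default 0.001).
#' @param jitter_ms Half-width of the jitter window, ms (default 50).
#' @param active_rate_min Electrodes firing below this rate (spikes/s) are
#'   excluded as nodes (default 0.1).
#' @param seed Integer seed; the inference is deterministic given a seed.
#' @return An object of class `mea_connectivity`: a list with `graph`
#'   (a directed [igraph][igraph::make_graph] with `weight` and `lag_ms`
#'   edge attributes), `nodes` (tibble `name`, `row`, `col`) and the call
#'   parameters.  With fewer than 2 active electrodes an empty graph is
#'   returned with a warning.
#' @export
infer_connectivity <- function(spikes, bin_ms = 5, max_lag_ms = 150,
                               n_surrogates = 20, alpha = 0.001,
                               jitter_ms = 50, active_rate_min = 0.1,
                               seed = 1L) {
  if (n_surrogates < 19) stop("`n_surrogates` must be >= 19", call. = FALSE)
  duration <- train_duration(spikes)
  grid <- train_grid(spikes)
  st <- spike_statistics(spikes, duration)
  act <- active_electrodes(st, active_rate_min)
  nodes <- tibble::tibble(name = paste0("e", act$row, "_", act$col),
                          row = act$row, col = act$col)
  empty_graph <- function() {
    g <- igraph::make_empty_graph(n = nrow(nodes), directed = TRUE)
    if (nrow(nodes)) g <- igraph::set_vertex_attr(g, "name", value = nodes$name)
    structure(list(graph = g, nodes = nodes,
                   params = list(bin_ms = bin_ms, max_lag_ms = max_lag_ms,
                                 n_surrogates = n_surrogates, alpha = alpha,
                                 jitter_ms = jitter_ms, seed = seed)),
              class = "mea_connectivity")
  }
  if (nrow(nodes) < 2) {
    warning("fewer than 2 active electrodes; returning an empty graph",
            call. = FALSE)
    return(empty_graph())
  }
  sp <- tibble::as_tibble(spikes)
  trains <- purrr::map(seq_len(nrow(nodes)), function(i)
    sort(sp$time_s[sp$row == nodes$row[i] & sp$col == nodes$col[i]]))
  edges_bins <- seq(0, max_lag_ms, by = bin_ms) / 1000
  z <- stats::qnorm(1 - alpha)
  res <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(nodes)), function(i) {
      purrr::map_dfr(seq_len(nrow(nodes)), function(j) {
        if (i == j) return(NULL)
        obs <- xcorr_counts(trains[[i]], trains[[j]], edges_bins)
        peak <- max(obs)
        if (peak == 0) return(NULL)
        surr <- vapply(seq_len(n_surrogates), function(s) {
          jb <- sort(trains[[j]] +
                       stats::runif(length(trains[[j]]), -jitter_ms / 1000,
                                    jitter_ms / 1000))
          max(xcorr_counts(trains[[i]], jb, edges_bins))
        }, numeric(1))
        m <- mean(surr); s <- stats::sd(surr)
        if (!(peak > m + z * max(s, .Machine$double.eps))) return(NULL)
        k <- which.max(obs)
        tibble::tibble(from = i, to = j,
                       weight = (peak - m) / max(s, .Machine$double.eps),
                       lag_ms = (edges_bins[k] + edges_bins[k + 1L]) / 2 * 1000)
      })
    })
  })
  g <- igraph::make_empty_graph(n = nrow(nodes), directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes$name)
  if (nrow(res)) {
    g <- igraph::add_edges(g, rbind(res$from, res$to))
    g <- igraph::set_edge_attr(g, "weight", value = res$weight)
    g <- igraph::set_edge_attr(g, "lag_ms", value = res$lag_ms)
  }
  structure(list(graph = g, nodes = nodes,
                 params = list(bin_ms = bin_ms, max_lag_ms = max_lag_ms,
                               n_surrogates = n_surrogates, alpha = alpha,
                               jitter_ms = jitter_ms, seed = seed)),
            class = "mea_connectivity")
}

# counts of (a, b) spike pairs with b - a in each (edge[k-1], edge[k]] lag bin
xcorr_counts <- function(a, b, edges_s) {
  if (!length(a) || !length(b)) return(numeric(length(edges_s) - 1L))
  cum <- vapply(edges_s, function(e) sum(findInterval(a + e, b)), numeric(1))
  diff(cum)
}

#' @export
print.mea_connectivity <- function(x, ...) {
  cat(sprintf("<mea_connectivity> %d nodes, %d directed edges\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Edge list of a connectivity graph
#'
#' @param x An `mea_connectivity` object.
#' @param ... Unused.
#' @return A tibble `(source_row, source_col, target_row, target_col,
#'   weight, lag_ms)`.
#' @export
tidy.mea_connectivity <- function(x, ...) {
  if (!igraph::ecount(x$graph)) {
    return(tibble::tibble(source_row = integer(), source_col = integer(),
                          target_row = integer(), target_col = integer(),
                          weight = numeric(), lag_ms = numeric()))
  }
  ends <- igraph::as_edgelist(x$graph, names = FALSE)
  tibble::tibble(
    source_row = x$nodes$row[ends[, 1]], source_col = x$nodes$col[ends[, 1]],
    target_row = x$nodes$row[ends[, 2]], target_col = x$nodes$col[ends[, 2]],
    weight = igraph::E(x$graph)$weight,
    lag_ms = igraph::E(x$graph)$lag_ms)
}

#' Graph metrics: clustering coefficient, path length, node degree
#'
#' Metrics are computed on the undirected simple view of the connectivity
#' graph (reciprocal and multiple edges collapse; electrodes in no edge are
#' dropped).  Per node: the local clustering coefficient (closed triangles
#' over possible triangles among neighbors; 0 where degree < 2), the mean
#' unweighted shortest-path length to all reachable nodes (unreachable
#' pairs excluded, self excluded), and the degree.
#' [glance()][generics::glance] pools medians/quartiles and reports the
#' path-length value at the `pl_fraction` cumulative node-count fraction
#' (default 0.70).
#'
#' @param g An `mea_connectivity` object (or an igraph).
#' @param pl_fraction Cumulative node-count fraction at which the pooled
#'   path-length value is read off (default 0.70).
#' @return A tibble of class `graph_metrics` with columns `name`, `row`,
#'   `col`, `degree`, `clustering`, `path_length`; empty (flagged via
#'   zero rows) for an empty graph.
#' @export
graph_metrics <- function(g, pl_fraction = 0.70) {
  ig <- if (inherits(g, "mea_connectivity")) g$graph else g
  nodes <- if (inherits(g, "mea_connectivity")) g$nodes else
    tibble::tibble(name = igraph::V(ig)$name %||%
                     as.character(seq_len(igraph::vcount(ig))),
                   row = NA_integer_, col = NA_integer_)
  gu <- igraph::as_undirected(ig, mode = "collapse")
  gu <- igraph::simplify(gu)
  deg <- igraph::degree(gu)
  keep <- which(deg > 0)
  out <- tibble::tibble(name = character(), row = integer(), col = integer(),
                        degree = integer(), clustering = numeric(),
                        path_length = numeric())
  if (length(keep)) {
    gs <- igraph::induced_subgraph(gu, keep)
    cc <- igraph::transitivity(gs, type = "local", isolates = "zero")
    d <- igraph::distances(gs)
    diag(d) <- NA
    d[!is.finite(d)] <- NA
    pl <- rowMeans(d, na.rm = TRUE)
    pl[is.nan(pl)] <- NA   # node reaching nothing (cannot happen if deg > 0)
    out <- tibble::tibble(
      name = nodes$name[keep], row = nodes$row[keep], col = nodes$col[keep],
      degree = as.integer(unname(igraph::degree(gs))),
      clustering = unname(cc), path_length = unname(pl))
  }
  structure(out, class = c("graph_metrics", class(tibble::tibble())),
            pl_fraction = pl_fraction)
}

#' @export
glance.graph_metrics <- function(x, ...) {
  f <- attr(x, "pl_fraction") %||% 0.70
  q <- function(v) stats::quantile(v, c(.25, .5, .75), na.rm = TRUE,
                                   names = FALSE)
  qd <- q(x$degree); qc <- q(x$clustering); qp <- q(x$path_length)
  tibble::tibble(
    n_nodes = nrow(x),
    degree_q1 = qd[1], degree_median = qd[2], degree_q3 = qd[3],
    cc_q1 = qc[1], cc_median = qc[2], cc_q3 = qc[3],
    pl_q1 = qp[1], pl_median = qp[2], pl_q3 = qp[3],
    pl_at_fraction = pl_at_cumulative_fraction(x$path_length, f))
}

#' Path-length value at a cumulative node-count fraction
#'
#' Sorts the per-node mean path lengths and reads off the value below
#' which `fraction` of the nodes fall (ceiling convention on the rank).
#'
#' @param pl Numeric vector of per-node path lengths.
#' @param fraction Cumulative fraction in (0, 1].
#' @return The path-length value, or NA when no finite values exist.
#' @export
pl_at_cumulative_fraction <- function(pl, fraction = 0.70) {
  pl <- sort(pl[is.finite(pl)])
  if (!length(pl)) return(NA_real_)
  pl[max(1L, ceiling(fraction * length(pl)))]
}

#' Classify nodes as senders, receivers or brokers
#'
#' Roles are read from the directed degrees: a node is a `sender` when its
#' out-degree exceeds `ratio` times its in-degree, a `receiver` when the
#' in-degree exceeds `ratio` times the out-degree, and a `broker`
#' otherwise.
#'
#' @param g An `mea_connectivity` object.
#' @param ratio Dominance ratio (default 2).
#' @return A tibble `(name, row, col, out_degree, in_degree, role)`.
#' @export
classify_node_roles <- function(g, ratio = 2) {
  stopifnot(inherits(g, "mea_connectivity"))
  outd <- igraph::degree(g$graph, mode = "out")
  ind <- igraph::degree(g$graph, mode = "in")
  role <- dplyr::case_when(outd > ratio * ind ~ "sender",
                           ind > ratio * outd ~ "receiver",
                           TRUE ~ "broker")
  tibble::tibble(name = g$nodes$name, row = g$nodes$row, col = g$nodes$col,
                 out_degree = as.integer(outd), in_degree = as.integer(ind),
                 role = role)
}
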