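# Co-medication co-reporting network: construction from within-ICSR drug
# co-occurrence, centralities, and the targeted-versus-random hub-removal
# robustness simulation.

#' Build the co-medication graph
#'
#' Undirected simple graph over all active substances (suspect union
#' concomitant); an edge joins two actives iff they co-occur in at least one
#' case, weighted by the number of co-reporting cases. No self-loops.
#'
#' @param cases Case-level tibble.
#' @param sep Intra-cell separator.
#' @return An `igraph` object with edge attribute `weight`.
#' @export
build_comed_graph <- function(cases, sep = ";") {
  actives <- Map(function(s, c) sort(unique(c(split_cell(s, sep), split_cell(c, sep)))),
                 cases$suspect_actives, cases$concomitant_actives)
  nodes <- sort(unique(unlist(actives)))
  pair_list <- lapply(actives, function(a) {
    if (length(a) < 2) return(NULL)
    t(combn(a, 2))
  })
  pairs <- do.call(rbind, pair_list)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (!is.null(pairs) && nrow(pairs)) {
    key <- paste(pairs[, 1], pairs[, 2], sep = "\r")
    w <- table(key)
    uv <- do.call(rbind, strsplit(names(w), "\r", fixed = TRUE))
    g <- igraph::add_edges(g, rbind(match(uv[, 1], nodes), match(uv[, 2], nodes)))
    igraph::E(g)$weight <- as.numeric(w)
  }
  g
}

#' Node centralities of the co-medication graph
#'
#' Unweighted degree and betweenness normalised to `[0, 1]` (by
#' `2 / ((n-1)(n-2))` for undirected graphs); betweenness is defined as 0
#' for graphs with fewer than 3 nodes.
#'
#' @param g igraph object from [build_comed_graph()].
#' @return Tibble `drug`, `degree`, `betweenness`.
#' @export
node_centrality <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0) abort("Empty graph.")
  btw <- if (n < 3) rep(0, n) else {
    igraph::betweenness(g, directed = FALSE, weights = NA, normalized = TRUE)
  }
  tibble::tibble(
    drug = igraph::V(g)$name,
    degree = as.numeric(igraph::degree(g)),
    betweenness = as.numeric(btw)
  )
}

# One removal trajectory; returns per-depth edge fraction removed and
# modularity of the greedy-modularity partition of the remaining graph.
removal_trajectory <- function(g, strategy, depths) {
  e0 <- igraph::ecount(g)
  cur <- g
  out_frac <- numeric(length(depths))
  out_mod <- numeric(length(depths))
  removed <- 0L
  for (k in seq_along(depths)) {
    target <- depths[k]
    while (removed < target && igraph::vcount(cur) > 0) {
      if (strategy == "targeted") {
        deg <- igraph::degree(cur)
        cand <- which(deg == max(deg))
        pick <- cand[[sample.int(length(cand), 1)]]
      } else {
        pick <- sample.int(igraph::vcount(cur), 1)
      }
      cur <- igraph::delete_vertices(cur, pick)
      removed <- removed + 1L
    }
    out_frac[k] <- if (e0 == 0) 0 else 1 - igraph::ecount(cur) / e0
    out_mod[k] <- if (igraph::ecount(cur) == 0) NA_real_ else {
      igraph::modularity(igraph::cluster_fast_greedy(cur, weights = NULL))
    }
  }
  list(frac = out_frac, modularity = out_mod)
}

#' Hub-removal robustness simulation
#'
#' Simulates node removal under two strategies: `"targeted"` removes the
#' current highest-degree node at each step (degree recomputed after every
#' removal; ties broken uniformly at random per replicate) and `"random"`
#' removes uniformly without replacement. At each depth the fraction of the
#' original edges removed and the modularity of the greedy-modularity
#' partition of the remaining graph are recorded; means and percentile 95%
#' CIs are taken over replicates.
#'
#' @param g igraph object.
#' @param strategies Removal strategies to simulate.
#' @param depths Integer vector of removal depths (number of nodes removed);
#'   must not exceed `vcount(g) - 1`.
#' @param replicates Replicates per strategy (default 1200).
#' @param seed Integer seed.
#' @return Tibble keyed by strategy x depth: `frac_edges_removed` (mean),
#'   `frac_lo`, `frac_hi`, `modularity` (mean), `mod_lo`, `mod_hi`,
#'   `replicates`.
#' @export
robustness_sim <- function(g, strategies = c("targeted", "random"),
                           depths = 0:10, replicates = 1200, seed = 1L) {
  if (igraph::vcount(g) == 0) abort("Empty graph.")
  if (max(depths) > igraph::vcount(g) - 1) {
    abort("`depths` must not exceed vcount(g) - 1.")
  }
  depths <- sort(unique(as.integer(depths)))
  seeds <- derive_seeds(seed, length(strategies) * replicates, salt = 7L)
  si <- 0L
  rows <- list()
  for (strategy in strategies) {
    fr <- matrix(NA_real_, nrow = replicates, ncol = length(depths))
    mo <- matrix(NA_real_, nrow = replicates, ncol = length(depths))
    for (r in seq_len(replicates)) {
      si <- si + 1L
      traj <- with_seed(seeds[si], removal_trajectory(g, strategy, depths))
      fr[r, ] <- traj$frac
      mo[r, ] <- traj$modularity
    }
    ci <- function(x) {
      x <- x[!is.na(x)]
      if (!length(x)) return(c(NA_real_, NA_real_, NA_real_))
      c(mean(x), quantile(x, 0.025, names = FALSE), quantile(x, 0.975, names = FALSE))
    }
    for (k in seq_along(depths)) {
      f <- ci(fr[, k]); m <- ci(mo[, k])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        strategy = strategy, depth = depths[k],
        frac_edges_removed = f[1], frac_lo = f[2], frac_hi = f[3],
        modularity = m[1], mod_lo = m[2], mod_hi = m[3],
        replicates = replicates
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Export a graph as a delimited edge list
#' @param g igraph object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_edge_list <- function(g, path) {
  el <- igraph::as_data_frame(g, what = "edges")
  names(el)[1:2] <- c("source", "target")
  if (!"weight" %in% names(el)) el$weight <- rep(1, nrow(el))
  readr::write_csv(tibble::as_tibble(el), path)
  invisible(path)
}
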