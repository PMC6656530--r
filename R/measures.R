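#' Network measures
#'
#' Computes the standard descriptive measures of a semantic network:
#' number of nodes, diameter, density, mean and median degree, average
#' shortest-path length (aspl) and global clustering coefficient
#' (transitivity: 3 x triangles / connected triplets). Diameter and aspl
#' are computed on the largest connected component, as they are undefined
#' on disconnected networks; on a single-node network they are reported as
#' `NA`, not 0.
#'
#' @param net semantic network.
#' @return one-row data frame with columns `n_nodes`, `n_edges`,
#'   `diameter`, `density`, `mean_degree`, `median_degree`, `aspl`,
#'   `clustering`.
#' @export
compute_measures <- function(net) {
  validate_network(net)
  n <- igraph::vcount(net)
  if (n == 0L) stop("empty network")
  deg <- igraph::degree(net)
  comp <- igraph::components(net)
  giant <- igraph::induced_subgraph(
    net, which(comp$membership == which.max(comp$csize)))
  has_paths <- igraph::vcount(giant) >= 2L
  clustering <- igraph::transitivity(net, type = "global")
  data.frame(
    n_nodes = n,
    n_edges = igraph::ecount(net),
    diameter = if (has_paths) igraph::diameter(giant) else NA_real_,
    density = if (n >= 2L) igraph::edge_density(net) else NA_real_,
    mean_degree = mean(deg),
    median_degree = median(deg),
    aspl = if (has_paths) igraph::mean_distance(giant) else NA_real_,
    clustering = if (is.nan(clustering)) NA_real_ else clustering)
}

#' Small-world coefficient
#'
#' `(C / C_rand) / (L / L_rand)` where `C` is the global clustering
#' coefficient, `L` the average shortest-path length (largest component),
#' and `C_rand`, `L_rand` are means over `n_random` Erdos-Renyi `G(n, m)`
#' graphs with the same node and edge count (the largest-component
#' convention applied to each). Coefficients above 1 indicate small-world
#' structure.
#'
#' @param net semantic network whose largest component has >= 3 nodes.
#' @param n_random number of random reference graphs.
#' @return the coefficient, or `NA` with a warning when the random
#'   baseline clustering is zero (tiny sparse graphs).
#' @export
smallworld_coefficient <- function(net, n_random = 100) {
  m <- compute_measures(net)
  if (is.na(m$clustering) || is.na(m$aspl))
    stop("small-world coefficient needs a component with at least 3 nodes")
  rand <- vapply(seq_len(n_random), function(k) {
    g <- igraph::sample_gnm(m$n_nodes, m$n_edges)
    comp <- igraph::components(g)
    giant <- igraph::induced_subgraph(
      g, which(comp$membership == which.max(comp$csize)))
    c(C = igraph::transitivity(g, type = "global"),
      L = if (igraph::vcount(giant) >= 2L) igraph::mean_distance(giant)
          else NA_real_)
  }, numeric(2))
  C_rand <- mean(rand["C", ], na.rm = TRUE)
  L_rand <- mean(rand["L", ], na.rm = TRUE)
  if (!is.finite(C_rand) || C_rand == 0) {
    warning("random baseline clustering is zero; small-world coefficient undefined")
    return(NA_real_)
  }
  (m$clustering / C_rand) / (m$aspl / L_rand)
}

#' Permutation ("mock") network ensemble
#'
#' Null model for size-corrected comparison: for each of `k` replicates,
#' the item order within every list of the corpus is independently
#' permuted (list membership and lengths preserved), a network is
#' re-estimated with the same estimator settings, and its measures are
#' computed. Every mock network has the same node set as the participant
#' network (the permutation does not change the vocabulary). Replicates
#' whose estimation fails are recorded and excluded from the means.
#'
#' @param corpus a [fluency_corpus()].
#' @param prior an [edge_prior()].
#' @param k number of mock replicates (default 50).
#' @param seed master seed; per-replicate permutation and search seeds are
#'   spawned from it.
#' @param ... passed on to [estimate_network()] (e.g. `patience`,
#'   `max_iters`).
#' @return object of class `mock_ensemble`: `measures` (k-row data frame,
#'   failed rows NA), `means` (named vector of per-measure mock means),
#'   `n_failed`, `seeds`.
#' @export
mock_ensemble <- function(corpus, prior = edge_prior(), k = 50, seed = NULL,
                          ...) {
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, k)
  rows <- vector("list", k)
  failed <- 0L
  for (r in seq_len(k)) {
    set.seed(seeds[r])
    perm <- fluency_corpus(corpus$participant_id, lapply(corpus$lists, function(fl) {
      fluency_list(fl$participant_id, fl$list_id,
                   if (length(fl$items) > 1L) sample(fl$items) else fl$items)
    }))
    fit <- tryCatch(estimate_network(perm, prior = prior, seed = seeds[r], ...),
                    error = function(e) NULL)
    if (is.null(fit)) {
      failed <- failed + 1L
      rows[[r]] <- NULL
    } else {
      m <- compute_measures(fit$network)
      m$p_emit <- fit$p_emit
      rows[[r]] <- m
    }
  }
  ok <- !vapply(rows, is.null, logical(1))
  measures <- do.call(rbind, rows[ok])
  if (failed > 0L)
    warning(sprintf("%d of %d mock replicates failed estimation and were excluded",
                    failed, k))
  means <- if (!is.null(measures)) colMeans(measures, na.rm = TRUE) else NULL
  structure(list(measures = measures, means = means, k = k,
                 n_failed = failed, seeds = seeds),
            class = "mock_ensemble")
}

#' @export
print.mock_ensemble <- function(x, ...) {
  cat(sprintf("<mock_ensemble: %d replicates (%d failed)>\n", x$k, x$n_failed))
  if (!is.null(x$means)) print(round(x$means, 3))
  invisible(x)
}

#' Delta metrics against a mock ensemble
#'
#' `delta = participant value - mean over mock networks`, per measure.
#' Small-worldness is excluded (it is already a ratio against random
#' networks) and so is `p_emit` (not inherently correlated with network
#' size); node and edge counts are excluded because mocks match them by
#' construction.
#'
#' @param participant one-row data frame from [compute_measures()].
#' @param ensemble a [mock_ensemble()].
#' @return named numeric vector of deltas (`delta_diameter`,
#'   `delta_density`, `delta_mean_degree`, `delta_median_degree`,
#'   `delta_aspl`, `delta_clustering`).
#' @export
delta_measures <- function(participant, ensemble) {
  if (is.null(ensemble$means)) stop("all mock replicates failed; deltas undefined")
  keep <- c("diameter", "density", "mean_degree", "median_degree",
            "aspl", "clustering")
  out <- vapply(keep, function(m)
    as.numeric(participant[[m]]) - as.numeric(ensemble$means[[m]]),
    numeric(1))
  setNames(out, paste0("delta_", keep))
}
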