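#' Filter taxa by overall relative abundance
#'
#' Keeps the taxa whose share of the grand total count is at least
#' `min_frac` (the usual pre-filter before co-occurrence analysis, default
#' 0.01% = 1e-4). The sample set is unchanged.
#'
#' @param table Abundance tibble.
#' @param min_frac Minimum taxon total / grand total, in `[0, 1)`.
#' @return The filtered abundance tibble.
#' @export
filter_by_relative_abundance <- function(table, min_frac = 1e-4) {
  stopifnot(min_frac >= 0, min_frac < 1)
  m <- abundance_matrix(table)
  keep <- colSums(m) / sum(m) >= min_frac
  if (!any(keep)) {
    abort("abundance filter removed every taxon; lower min_frac")
  }
  dplyr::select(table, "sample", dplyr::all_of(colnames(m)[keep]))
}

#' Pairwise Spearman correlation matrix with p-values
#'
#' Spearman's rho on average-ranked data (tie-corrected) for every taxon
#' pair, with two-sided p-values from the t approximation
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} on \eqn{n - 2} degrees of
#' freedom. For small studies (`n <= 10`) `p_method = "exact"` uses the
#' exact null distribution of the rank statistic instead (via
#' [stats::cor.test()]; the t approximation is substituted where ties make
#' the exact distribution unavailable). Zero-variance taxa have undefined
#' correlations: their entries are `NA` and they are reported in the
#' `degenerate` field.
#'
#' @param table Abundance tibble with at least 4 samples.
#' @param p_method `"t"` (default) or `"exact"`.
#' @return List with class `"emnet_spearman"`: `rho` and `p` matrices
#'   (diagonal 1 and 0), `n`, `degenerate` (names of zero-variance taxa).
#' @export
spearman_matrix <- function(table, p_method = c("t", "exact")) {
  p_method <- match.arg(p_method)
  m <- abundance_matrix(table)
  n <- nrow(m)
  if (n < 4L) abort("need at least 4 samples for correlation p-values")
  if (p_method == "exact" && n > 10L) {
    abort("exact p-values are only supported for n <= 10")
  }
  degenerate <- colnames(m)[apply(m, 2, function(x) sd(x) == 0)]
  rho <- suppressWarnings(cor(m, method = "spearman"))
  rho[degenerate, ] <- NA_real_
  rho[, degenerate] <- NA_real_
  if (p_method == "t") {
    r2 <- pmin(rho^2, 1)
    tval <- abs(rho) * sqrt((n - 2) / pmax(1 - r2, .Machine$double.eps))
    p <- 2 * pt(tval, df = n - 2, lower.tail = FALSE)
    p[r2 >= 1] <- 0
  } else {
    p <- matrix(NA_real_, ncol(m), ncol(m), dimnames = dimnames(rho))
    ok <- setdiff(colnames(m), degenerate)
    for (i in seq_along(ok)) {
      for (j in seq_len(i - 1L)) {
        ct <- suppressWarnings(
          stats::cor.test(m[, ok[i]], m[, ok[j]], method = "spearman",
                          exact = TRUE)
        )
        p[ok[i], ok[j]] <- p[ok[j], ok[i]] <- ct$p.value
      }
    }
  }
  diag(rho) <- 1
  diag(p) <- 0
  structure(list(rho = rho, p = p, n = n, degenerate = degenerate),
            class = "emnet_spearman")
}

#' Build a signed co-occurrence network
#'
#' Thresholds a Spearman correlation matrix into an undirected signed
#' graph: an edge joins taxa \eqn{i, j} when \eqn{|\rho_{ij}| \ge}
#' `r_cut` and \eqn{p_{ij} \le} `p_cut`. Positive and negative
#' correlations are kept with their sign (putative cooperation vs
#' competition). Taxa left without any edge are dropped from the graph but
#' counted in the provenance. No multiple-testing correction is applied by
#' default; `adjust_p = "BH"` switches the threshold to
#' Benjamini-Hochberg-adjusted p-values.
#'
#' @param table Abundance tibble, already abundance-filtered.
#' @param r_cut,p_cut Edge thresholds.
#' @param taxonomy Optional tibble with columns `taxon`, `genus`,
#'   `kingdom` used to annotate nodes.
#' @param provenance Free-text label (source table / forest-type subset).
#' @param adjust_p `"none"` (default) or `"BH"`.
#' @param p_method Passed to [spearman_matrix()].
#' @return An `emnet_network`: list of `graph` (igraph with edge
#'   attributes `rho`, `p`, `sign`), `params`, `provenance`.
#' @examples
#' tab <- tibble::tibble(sample = paste0("s", 1:6),
#'                       a = 1:6, b = c(2, 1, 4, 3, 6, 5) * 10, c = 6:1)
#' build_network(tab, r_cut = 0.6, p_cut = 0.05)
#' @export
build_network <- function(table, r_cut = 0.6, p_cut = 0.001,
                          taxonomy = NULL, provenance = "",
                          adjust_p = c("none", "BH"),
                          p_method = "t") {
  adjust_p <- match.arg(adjust_p)
  sp <- spearman_matrix(table, p_method = p_method)
  rho <- sp$rho
  p <- sp$p
  if (adjust_p == "BH") {
    ut <- upper.tri(p)
    p[ut] <- stats::p.adjust(p[ut], method = "BH")
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  keep <- !is.na(rho) & abs(rho) >= r_cut & p <= p_cut
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  taxa <- colnames(rho)
  rho_v <- rho[keep]
  p_v <- p[keep]
  edges <- tibble::tibble(
    from = taxa[idx[, 1]], to = taxa[idx[, 2]],
    rho = rho_v, p = p_v, sign = ifelse(rho_v > 0, 1L, -1L)
  )
  if (nrow(edges) == 0L) {
    warn("no edge passed the thresholds; returning an empty network")
  }
  nodes <- sort(unique(c(edges$from, edges$to)))
  vert <- tibble::tibble(name = nodes)
  if (!is.null(taxonomy)) {
    ann <- dplyr::select(taxonomy, taxon = 1, dplyr::any_of(c("genus", "kingdom")))
    vert <- dplyr::left_join(vert, ann, by = c(name = "taxon"))
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vert)
  new_emnet_network(
    g,
    params = list(r_cut = r_cut, p_cut = p_cut, adjust_p = adjust_p,
                  p_method = p_method, n_samples = sp$n,
                  n_taxa_tested = length(taxa),
                  n_isolated = length(taxa) - length(nodes)),
    provenance = provenance
  )
}

#' Topology summary of a co-occurrence network
#'
#' One row of whole-network metrics: node and edge counts, the
#' positive/negative edge tally and their ratio, average degree, average
#' shortest-path distance over reachable pairs, graph density, degree
#' assortativity, and mean betweenness / degree / eigenvector centrality.
#' All path- and degree-based metrics are computed on the unsigned
#' topology; only the edge tally uses the signs. Eigenvector centrality is
#' computed on the largest connected component. Metrics that are undefined
#' (empty network; assortativity on a degree-regular graph; ratio with no
#' negative edges) are `NA` and listed in the `undefined` attribute.
#'
#' @param net An `emnet_network`.
#' @param betweenness Reduction for node betweenness: `"mean"` of
#'   normalized node values (default) or `"centralization"` (Freeman graph
#'   centralization).
#' @return A one-row tibble with class `"emnet_topology"`.
#' @export
network_topology <- function(net, betweenness = c("mean", "centralization")) {
  betweenness <- match.arg(betweenness)
  stopifnot(inherits(net, "emnet_network"))
  g <- net$graph
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  undefined <- character()
  if (n == 0L) {
    out <- tibble::tibble(
      node_num = 0L, edge_num = 0L, positive_edges = 0L, negative_edges = 0L,
      pos_neg_ratio = NA_real_, average_degree = NA_real_,
      average_distance = NA_real_, density = NA_real_,
      assortativity = NA_real_, betweenness_centrality = NA_real_,
      degree_centrality = NA_real_, eigenvector_centrality = NA_real_
    )
    undefined <- setdiff(names(out), c("node_num", "edge_num",
                                       "positive_edges", "negative_edges"))
    return(structure(out, class = c("emnet_topology", class(out)),
                     undefined = undefined))
  }
  sgn <- if (e) igraph::E(g)$sign else integer()
  pos <- sum(sgn > 0)
  neg <- sum(sgn < 0)
  ratio <- if (neg == 0) { undefined <- c(undefined, "pos_neg_ratio"); NA_real_ } else pos / neg
  deg <- igraph::degree(g)
  assort <- suppressWarnings(igraph::assortativity_degree(g))
  if (is.nan(assort)) { undefined <- c(undefined, "assortativity"); assort <- NA_real_ }
  btw <- igraph::betweenness(g, normalized = TRUE)
  btw_val <- if (betweenness == "mean") mean(btw) else {
    if (n > 2) sum(max(btw) - btw) / (n - 1) else 0
  }
  comps <- igraph::components(g)
  lcc <- igraph::induced_subgraph(g, which(comps$membership == which.max(comps$csize)))
  eig <- mean(igraph::eigen_centrality(lcc)$vector)
  out <- tibble::tibble(
    node_num = n, edge_num = e, positive_edges = pos, negative_edges = neg,
    pos_neg_ratio = ratio,
    average_degree = mean(deg),
    average_distance = igraph::mean_distance(g, unconnected = TRUE),
    density = igraph::edge_density(g),
    assortativity = assort,
    betweenness_centrality = btw_val,
    degree_centrality = if (n > 1) mean(deg / (n - 1)) else NA_real_,
    eigenvector_centrality = eig
  )
  structure(out, class = c("emnet_topology", class(out)), undefined = undefined)
}

#' Per-sample induced subnetworks
#'
#' For each sample, takes the subgraph of the network induced by the taxa
#' with a positive count in that sample, and records its node number, edge
#' number, and mean normalized betweenness centrality — giving every
#' sample its own topology. A sample containing no network taxon gets
#' zeros.
#'
#' @param net An `emnet_network` built from (a filtered version of)
#'   `table`.
#' @param table Abundance tibble whose samples to project onto the
#'   network.
#' @return A tibble with class `"emnet_subnet"`: `sample`, `node_num`,
#'   `edge_num`, `betweenness_centrality`.
#' @export
sample_subnetworks <- function(net, table) {
  stopifnot(inherits(net, "emnet_network"))
  m <- abundance_matrix(table)
  nodes <- igraph::V(net$graph)$name
  rows <- purrr::map(rownames(m), function(s) {
    present <- intersect(nodes, colnames(m)[m[s, ] > 0])
    sg <- igraph::induced_subgraph(net$graph, present)
    nn <- igraph::vcount(sg)
    tibble::tibble(
      sample = s,
      node_num = nn,
      edge_num = igraph::ecount(sg),
      betweenness_centrality =
        if (nn == 0) 0 else mean(igraph::betweenness(sg, normalized = TRUE))
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("emnet_subnet", class(out)))
}

#' Multi-complexity index of per-sample subnetworks
#'
#' The single-index multi-complexity ("Multi-net") of each sample is the
#' mean of the z-standardized subnetwork metrics — node number, edge
#' number, and betweenness centrality — standardized across the full
#' sample set (mean 0, sample SD 1). A metric that is constant across
#' samples carries no information; its z-score is defined as 0 for every
#' sample and the metric is reported in the `constant_metrics` attribute.
#'
#' @param metrics An `emnet_subnet` tibble (>= 2 samples).
#' @return The input tibble with a `multi_net` column appended.
#' @export
multi_net <- function(metrics) {
  stopifnot(nrow(metrics) >= 2L)
  cols <- c("node_num", "edge_num", "betweenness_centrality")
  z <- purrr::map(metrics[cols], function(x) {
    s <- sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
  constant <- cols[vapply(metrics[cols], function(x) sd(x) == 0, logical(1))]
  out <- dplyr::mutate(metrics, multi_net = purrr::reduce(z, `+`) / length(z))
  structure(out, class = unique(c("emnet_subnet", class(out))),
            constant_metrics = constant)
}

#' Node roles from within- and among-module connectivity (Zi-Pi)
#'
#' Partitions the unsigned network into modules by greedy modularity
#' maximization (deterministic; `method = "louvain"` uses seeded Louvain
#' instead) and computes, for every node, the within-module degree z-score
#' \deqn{Z_i = (k_i^{in} - \bar{k}^{in}_{m(i)}) / s^{in}_{m(i)}}
#' and the participation coefficient
#' \deqn{P_i = 1 - \sum_m (k_{im} / k_i)^2.}
#' Roles follow the classical thresholds: peripherals (`Zi <= zi_cut`,
#' `Pi <= pi_cut`), connectors (`Zi <= zi_cut`, `Pi > pi_cut`), module
#' hubs (`Zi > zi_cut`, `Pi <= pi_cut`), network hubs (both exceeded);
#' boundary values fall in the lower category. Nodes in modules with zero
#' within-degree spread (including singleton modules) get `Zi = 0` and are
#' flagged.
#'
#' @param net An `emnet_network` with at least one edge.
#' @param seed Seed for stochastic module detection methods.
#' @param zi_cut,pi_cut Role thresholds.
#' @param method `"fast_greedy"` (default) or `"louvain"`.
#' @return A tibble with class `"emnet_roles"`: `node`, `module`,
#'   `degree`, `zi`, `pi`, `role`, `zi_degenerate`.
#' @export
zi_pi <- function(net, seed = 1L, zi_cut = 2.5, pi_cut = 0.62,
                  method = c("fast_greedy", "louvain")) {
  method <- match.arg(method)
  stopifnot(inherits(net, "emnet_network"))
  g <- net$graph
  if (igraph::ecount(g) == 0L) abort("node roles need a network with edges")
  comm <- switch(method,
    fast_greedy = igraph::cluster_fast_greedy(g, weights = NULL),
    louvain = {
      set.seed(seed)
      igraph::cluster_louvain(g, weights = NULL)
    }
  )
  mem <- igraph::membership(comm)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  deg <- rowSums(adj)
  # k_im: links of node i into module m
  mods <- sort(unique(mem))
  k_im <- vapply(mods, function(mm) rowSums(adj[, mem == mm, drop = FALSE]),
                 numeric(length(deg)))
  k_in <- k_im[cbind(seq_along(deg), match(mem, mods))]
  zi <- numeric(length(deg))
  zi_flag <- logical(length(deg))
  for (mm in mods) {
    in_m <- mem == mm
    s <- sd(k_in[in_m])
    if (sum(in_m) < 2L || is.na(s) || s == 0) {
      zi[in_m] <- 0
      zi_flag[in_m] <- TRUE
    } else {
      zi[in_m] <- (k_in[in_m] - mean(k_in[in_m])) / s
    }
  }
  pi <- 1 - rowSums((k_im / deg)^2)
  role <- dplyr::case_when(
    zi <= zi_cut & pi <= pi_cut ~ "peripheral",
    zi <= zi_cut & pi > pi_cut ~ "connector",
    zi > zi_cut & pi <= pi_cut ~ "module hub",
    TRUE ~ "network hub"
  )
  out <- tibble::tibble(
    node = igraph::V(g)$name,
    module = as.integer(mem),
    degree = as.integer(deg),
    zi = zi, pi = unname(pi), role = role,
    zi_degenerate = zi_flag
  )
  structure(out, class = c("emnet_roles", class(out)),
            zi_cut = zi_cut, pi_cut = pi_cut, method = method)
}

#' Correlate keystone-taxon abundance with diversity indicators
#'
#' Keystone taxa are the non-peripheral nodes (connectors, module hubs,
#' network hubs). For each keystone, its per-sample relative abundance is
#' correlated (Spearman) with every numeric indicator supplied — alpha
#' diversity, per-sample beta summaries, subnetwork topology, plant
#' richness, or any other per-sample column.
#'
#' @param roles An `emnet_roles` table.
#' @param table Abundance tibble (used for relative abundances).
#' @param indicators Tibble with a `sample` column and numeric indicator
#'   columns, aligned with `table`'s samples.
#' @return Tibble: `taxon`, `role`, `indicator`, `rho`, `p_value`,
#'   `undefined` (TRUE where a zero-variance series makes the correlation
#'   undefined).
#' @export
keystone_diversity_correlations <- function(roles, table, indicators) {
  keys <- roles$node[roles$role != "peripheral"]
  if (!length(keys)) {
    warn("no keystone (non-peripheral) taxa in the network")
    return(tibble::tibble(taxon = character(), role = character(),
                          indicator = character(), rho = double(),
                          p_value = double(), undefined = logical()))
  }
  m <- abundance_matrix(table)
  rel <- sweep(m, 1, rowSums(m), "/")
  ind <- dplyr::semi_join(indicators, tibble::tibble(sample = rownames(m)),
                          by = "sample")
  ind <- ind[match(rownames(m), ind$sample), ]
  num_cols <- names(ind)[vapply(ind, is.numeric, logical(1))]
  n <- nrow(rel)
  purrr::map_dfr(keys, function(k) {
    x <- rel[, k]
    purrr::map_dfr(num_cols, function(v) {
      y <- ind[[v]]
      bad <- sd(x) == 0 || sd(y) == 0
      if (bad) {
        rho <- NA_real_; p <- NA_real_
      } else {
        rho <- suppressWarnings(cor(x, y, method = "spearman"))
        tval <- abs(rho) * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
        p <- if (rho^2 >= 1) 0 else 2 * pt(tval, n - 2, lower.tail = FALSE)
      }
      tibble::tibble(taxon = k, role = roles$role[roles$node == k],
                     indicator = v, rho = rho, p_value = p, undefined = bad)
    })
  })
}
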