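# Independent brute-force oracles used to check the package implementations.
# These deliberately share no code with the package: plain loops and set
# arithmetic only.

oracle_alpha <- function(x) {
  x <- x[x > 0]
  p <- x / sum(x)
  shannon <- 0
  simpson_sum <- 0
  for (pi in p) {
    shannon <- shannon - pi * log(pi)
    simpson_sum <- simpson_sum + pi^2
  }
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  chao1 <- length(x) + f1 * (f1 - 1) / (2 * (f2 + 1))
  rare <- x[x <= 10]
  s_abund <- sum(x > 10)
  if (length(rare) == 0) {
    ace <- s_abund
  } else {
    n_rare <- sum(rare)
    c_ace <- 1 - sum(rare == 1) / n_rare
    if (c_ace == 0) {
      ace <- chao1
    } else {
      num <- 0
      for (k in 1:10) num <- num + k * (k - 1) * sum(rare == k)
      g2 <- max(length(rare) / c_ace * num / (n_rare * (n_rare - 1)) - 1, 0)
      ace <- s_abund + length(rare) / c_ace + sum(rare == 1) / c_ace * g2
    }
  }
  list(richness = length(x), shannon = shannon, simpson = 1 - simpson_sum,
       chao1 = chao1, ace = ace)
}

oracle_beta_pair <- function(x, y) {
  sx <- which(x > 0)
  sy <- which(y > 0)
  a <- length(intersect(sx, sy))
  b <- length(setdiff(sx, sy))
  cc <- length(setdiff(sy, sx))
  sor <- (b + cc) / (2 * a + b + cc)
  sim <- if (min(b, cc) == 0) 0 else min(b, cc) / (a + min(b, cc))
  list(sor = sor, sim = sim, sne = sor - sim)
}

oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  mx <- mean(rx)
  my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# random count table with sample ids, for property tests
random_table <- function(n_samples, n_taxa, lambda = 3, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_samples * n_taxa, lambda), n_samples, n_taxa,
              dimnames = list(paste0("s", seq_len(n_samples)),
                              paste0("t", seq_len(n_taxa))))
  # guarantee every sample has at least one taxon
  empty <- rowSums(m) == 0
  m[empty, 1] <- 1
  tibble::as_tibble(m, rownames = "sample")
}

# tiny graph fixture as an emnet_network: edge list + signs
toy_network <- function(edges, signs = rep(1L, nrow(edges)), rho = NULL) {
  if (nrow(edges) == 0L) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    igraph::E(g)$sign <- integer()
  } else {
    rho <- rho %||% (signs * 0.9)
    g <- igraph::graph_from_data_frame(
      data.frame(from = edges[, 1], to = edges[, 2],
                 rho = rho, p = 1e-4, sign = signs),
      directed = FALSE
    )
  }
  emnet:::new_emnet_network(g, params = list(r_cut = 0.6, p_cut = 0.05))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
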