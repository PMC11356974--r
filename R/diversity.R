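#' Alpha diversity of each sample
#'
#' Computes the five standard within-sample diversity indicators from a
#' count table: observed richness, Shannon entropy (nats,
#' \eqn{-\sum p_i \ln p_i}), Simpson diversity, Chao1 and ACE richness
#' estimators.
#'
#' Simpson is reported as Gini-Simpson \eqn{1 - \sum p_i^2} by default;
#' `simpson = "lambda"` gives the concentration \eqn{\sum p_i^2} and
#' `"inverse"` gives \eqn{1 / \sum p_i^2}. Chao1 uses the bias-corrected
#' form \eqn{S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))} (defined even when
#' no doubletons exist); `chao1 = "classic"` gives
#' \eqn{S_{obs} + F_1^2 / (2 F_2)}. ACE uses the usual rare/abundant split
#' at `ace_cutoff` (10) individuals with the coverage-based coefficient of
#' variation, truncated at 0; when every rare taxon is a singleton the
#' sample coverage is 0 and ACE falls back to Chao1.
#'
#' @param table Abundance tibble (`sample` column + numeric taxon columns).
#' @param simpson Simpson variant to report.
#' @param chao1 Chao1 variant.
#' @param ace_cutoff Abundance cutoff separating rare from abundant taxa.
#' @return A tibble with class `"emnet_alpha"`: one row per sample with
#'   `richness`, `shannon`, `simpson`, `chao1`, `ace`, and sequencing
#'   `depth`. The variants used are recorded in attributes.
#' @examples
#' tab <- tibble::tibble(sample = "s1", a = 5, b = 5, c = 5, d = 5)
#' alpha_diversity(tab)
#' @export
alpha_diversity <- function(table,
                            simpson = c("gini", "lambda", "inverse"),
                            chao1 = c("bias_corrected", "classic"),
                            ace_cutoff = 10) {
  simpson <- match.arg(simpson)
  chao1 <- match.arg(chao1)
  m <- abundance_matrix(table)
  empty <- rownames(m)[rowSums(m) == 0]
  if (length(empty)) {
    abort(paste0("sample(s) with no positive counts: ",
                 paste(empty, collapse = ", ")))
  }
  lambda <- unname(vegan::diversity(m, index = "invsimpson")^-1)
  chao1_vals <- unname(apply(m, 1, chao1_estimate, form = chao1))
  ace_vals <- unname(apply(m, 1, ace_estimate, cutoff = ace_cutoff,
                           chao1_form = chao1))
  out <- tibble::tibble(
    sample = rownames(m),
    richness = as.integer(rowSums(m > 0)),
    shannon = unname(vegan::diversity(m, index = "shannon")),
    simpson = switch(simpson,
      gini = 1 - lambda,
      lambda = lambda,
      inverse = 1 / lambda
    ),
    chao1 = chao1_vals,
    ace = ace_vals,
    depth = unname(rowSums(m))
  )
  structure(out, class = c("emnet_alpha", class(out)),
            simpson_variant = simpson, chao1_variant = chao1,
            ace_cutoff = ace_cutoff)
}

chao1_estimate <- function(x, form = "bias_corrected") {
  x <- x[x > 0]
  s_obs <- length(x)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (form == "classic") {
    if (f2 == 0) return(s_obs + f1 * (f1 - 1) / 2) # usual f2 = 0 fallback
    return(s_obs + f1^2 / (2 * f2))
  }
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

ace_estimate <- function(x, cutoff = 10, chao1_form = "bias_corrected") {
  x <- x[x > 0]
  rare <- x[x <= cutoff]
  s_abund <- sum(x > cutoff)
  s_rare <- length(rare)
  if (s_rare == 0) return(s_abund)
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  c_ace <- 1 - f1 / n_rare
  if (c_ace == 0) return(chao1_estimate(x, chao1_form))
  fk <- tabulate(rare, nbins = cutoff)
  k <- seq_len(cutoff)
  gamma2 <- max(
    s_rare / c_ace * sum(k * (k - 1) * fk) / (n_rare * (n_rare - 1)) - 1,
    0
  )
  s_abund + s_rare / c_ace + f1 / c_ace * gamma2
}

#' Partition Sorensen beta diversity into turnover and nestedness
#'
#' From presence/absence (count > 0), computes the pairwise Sorensen
#' dissimilarity and its Baselga partition for every sample pair: with
#' \eqn{a} shared taxa and \eqn{b}, \eqn{c} taxa unique to each sample,
#' \deqn{\beta_{sor} = (b+c)/(2a+b+c), \quad
#'       \beta_{sim} = \min(b,c)/(a+\min(b,c)), \quad
#'       \beta_{sne} = \beta_{sor} - \beta_{sim}.}
#' \eqn{\beta_{sim}} captures species turnover (replacement) and
#' \eqn{\beta_{sne}} the nestedness-resultant component; they sum exactly
#' to \eqn{\beta_{sor}}. Multiple-site analogues over all samples are
#' computed with the matching multiple-site formulas.
#'
#' Per-sample summaries reduce each pairwise matrix to one value per plot.
#' The default is the mean dissimilarity of a sample to all others;
#' `summary = "lcbd"` instead reports local contributions to beta
#' diversity (squared-deviation decomposition of the Gower-centered
#' dissimilarity matrix), normalized to sum to 1.
#'
#' @param table Abundance tibble; at least two samples.
#' @param summary Per-sample reduction: `"mean"` or `"lcbd"`.
#' @return A list with class `"emnet_beta"`: matrices `beta_sor`,
#'   `beta_sim`, `beta_sne`; `summary` tibble with per-sample `BetaSOR`,
#'   `BetaSIM`, `BetaSNE`; `multi_site` tibble with the multiple-site
#'   values; `summary_method`.
#' @examples
#' tab <- tibble::tibble(sample = c("s1", "s2"),
#'                       a = c(1, 1), b = c(1, 0), c = c(0, 1))
#' beta_partition(tab)$beta_sor
#' @export
beta_partition <- function(table, summary = c("mean", "lcbd")) {
  summary <- match.arg(summary)
  m <- abundance_matrix(table)
  if (nrow(m) < 2L) abort("beta partition needs at least two samples")
  pa <- (m > 0) * 1
  empty <- rownames(pa)[rowSums(pa) == 0]
  if (length(empty)) {
    abort(paste0("sample(s) with no taxa: ", paste(empty, collapse = ", ")))
  }
  s <- rowSums(pa)
  shared <- pa %*% t(pa)
  b <- outer(s, rep(1, length(s))) - shared # taxa unique to the row sample
  cc <- t(b)
  min_bc <- pmin(b, cc)
  max_bc <- pmax(b, cc)
  beta_sor <- (b + cc) / (2 * shared + b + cc)
  beta_sim <- min_bc / (shared + min_bc)
  beta_sim[min_bc == 0] <- 0 # covers identical samples and pure nestedness
  beta_sne <- beta_sor - beta_sim
  diag(beta_sor) <- diag(beta_sim) <- diag(beta_sne) <- 0
  dimnames(beta_sor) <- dimnames(beta_sim) <- dimnames(beta_sne) <-
    list(rownames(pa), rownames(pa))

  per_sample <- switch(summary,
    mean = function(d) rowSums(d) / (nrow(d) - 1),
    lcbd = lcbd_from_dissimilarity
  )
  smry <- tibble::tibble(
    sample = rownames(pa),
    BetaSOR = unname(per_sample(beta_sor)),
    BetaSIM = unname(per_sample(beta_sim)),
    BetaSNE = unname(per_sample(beta_sne))
  )

  ut <- upper.tri(shared)
  sum_min <- sum(min_bc[ut])
  sum_max <- sum(max_bc[ut])
  core <- sum(s) - sum(colSums(pa) > 0) # sum S_i - S_T
  ms_sim <- sum_min / (core + sum_min)
  ms_sor <- (sum_min + sum_max) / (2 * core + sum_min + sum_max)
  multi_site <- tibble::tibble(
    BetaSOR = ms_sor, BetaSIM = ms_sim, BetaSNE = ms_sor - ms_sim
  )

  structure(
    list(beta_sor = beta_sor, beta_sim = beta_sim, beta_sne = beta_sne,
         summary = smry, multi_site = multi_site, summary_method = summary),
    class = "emnet_beta"
  )
}

lcbd_from_dissimilarity <- function(d) {
  a <- -0.5 * d^2
  g <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  # non-Euclidean dissimilarities can give tiny negative diagonal terms
  ss <- pmax(diag(g), 0)
  if (sum(ss) <= 0) return(rep(0, nrow(d)))
  ss / sum(ss)
}

#' @export
print.emnet_beta <- function(x, ...) {
  cat(sprintf("<emnet_beta> %d samples (%s summary)\n",
              nrow(x$beta_sor), x$summary_method))
  cat("multiple-site: ")
  print(as.data.frame(x$multi_site), row.names = FALSE)
  invisible(x)
}
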