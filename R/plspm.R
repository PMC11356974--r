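#' Specify a PLS path model
#'
#' A path model is a set of latent blocks — each measured by one or more
#' indicator columns — connected by a directed acyclic inner model. The
#' study's model has four blocks: plant diversity (richness), abiotic
#' factors (SOC, TN, LC, LP), biotic factors (assortativity, average
#' distance, eigenvector centrality of the cross-kingdom network), and EM
#' fungal diversity (alpha indices, the first two principal-coordinate
#' axes of the Bray-Curtis matrix, and network topology including the
#' multi-complexity index).
#'
#' @param blocks Named list: block name -> character vector of indicator
#'   columns. An indicator may appear in exactly one block.
#' @param paths Two-column data frame (`from`, `to`) of directed inner
#'   edges between block names. Must be acyclic.
#' @return A list with class `"emnet_plspm_spec"`: `blocks`, `paths`, and
#'   `inner` (logical adjacency matrix in topological order).
#' @export
plspm_spec <- function(blocks, paths) {
  stopifnot(is.list(blocks), !is.null(names(blocks)),
            all(c("from", "to") %in% names(paths)))
  ind <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(ind)) {
    abort(paste0("indicator(s) in more than one block: ",
                 paste(unique(ind[duplicated(ind)]), collapse = ", ")))
  }
  lat <- names(blocks)
  if (!all(c(paths$from, paths$to) %in% lat)) {
    abort("paths refer to unknown blocks")
  }
  adj <- matrix(FALSE, length(lat), length(lat), dimnames = list(lat, lat))
  adj[cbind(paths$from, paths$to)] <- TRUE # adj[from, to]
  ord <- topological_order(adj)
  if (is.null(ord)) abort("inner model has a cycle; it must be acyclic")
  adj <- adj[ord, ord]
  structure(list(blocks = blocks[ord], paths = paths, inner = adj),
            class = "emnet_plspm_spec")
}

topological_order <- function(adj) {
  remaining <- rownames(adj)
  ord <- character()
  while (length(remaining)) {
    indeg <- colSums(adj[remaining, remaining, drop = FALSE])
    src <- remaining[indeg == 0]
    if (!length(src)) return(NULL)
    ord <- c(ord, src[1])
    remaining <- setdiff(remaining, src[1])
  }
  ord
}

#' Ordination axes for the beta-diversity block
#'
#' Returns sample scores on the first `k` axes. Given a symmetric
#' dissimilarity matrix (e.g. Bray-Curtis), performs classical principal
#' coordinates analysis (eigendecomposition of the double-centered
#' matrix); given a data table, performs centered PCA. Axis signs are
#' fixed by making the largest-magnitude loading (PCA) or score (PCoA)
#' positive so results do not flip between runs.
#'
#' @param x Abundance tibble / numeric matrix of variables, or a symmetric
#'   dissimilarity matrix (class `dist` or square matrix with zero
#'   diagonal).
#' @param k Number of axes (`k <= n - 1`).
#' @return Tibble: `sample` plus `axis1 ... axisk`.
#' @export
pca_axes <- function(x, k = 2L) {
  if (inherits(x, "dist")) x <- as.matrix(x)
  is_dissim <- is.matrix(x) && nrow(x) == ncol(x) &&
    all(abs(diag(x)) < 1e-12)
  if (is_dissim) {
    if (!isSymmetric(unname(x), tol = 1e-8)) {
      abort("dissimilarity matrix must be symmetric")
    }
    if (k > nrow(x) - 1L) abort("k must be at most n - 1")
    sc <- cmdscale(stats::as.dist(x), k = k)
    # pad if the matrix is rank-deficient and cmdscale returns fewer axes
    if (ncol(sc) < k) sc <- cbind(sc, matrix(0, nrow(sc), k - ncol(sc)))
    for (j in seq_len(k)) {
      if (sc[which.max(abs(sc[, j])), j] < 0) sc[, j] <- -sc[, j]
    }
    ids <- rownames(x) %||% paste0("s", seq_len(nrow(x)))
  } else {
    if (tibble::is_tibble(x) || is.data.frame(x)) {
      ids <- if (!is.null(x[["sample"]])) as.character(x[["sample"]]) else
        paste0("s", seq_len(nrow(x)))
      m <- as.matrix(x[vapply(x, is.numeric, logical(1))])
    } else {
      m <- as.matrix(x)
      ids <- rownames(m) %||% paste0("s", seq_len(nrow(m)))
    }
    if (k > nrow(m) - 1L) abort("k must be at most n - 1")
    pc <- prcomp(m, center = TRUE, scale. = FALSE)
    sc <- pc$x[, seq_len(k), drop = FALSE]
    for (j in seq_len(k)) {
      flip <- pc$rotation[which.max(abs(pc$rotation[, j])), j] < 0
      if (flip) sc[, j] <- -sc[, j]
    }
  }
  colnames(sc) <- paste0("axis", seq_len(k))
  tibble::tibble(sample = ids, !!!as.data.frame(sc))
}

#' Fit a partial least-squares path model
#'
#' Lohmoller-style alternating estimation: latent scores are block-wise
#' weighted sums of standardized indicators; inner proxies combine
#' neighboring latents (path scheme by default: regression weights toward
#' predecessors, correlations toward successors); outer weights are
#' updated in mode A (reflective, covariance with the inner proxy) and the
#' loop runs until the largest absolute weight change is below `tol`.
#' Inner path coefficients are then OLS regressions of each endogenous
#' latent on its predecessors; block communalities, per-endogenous
#' \eqn{R^2}, and the goodness of fit
#' \eqn{GoF = \sqrt{\overline{\mathrm{communality}} \times \overline{R^2}}}
#' (communalities averaged over blocks with more than one indicator)
#' follow. Path uncertainty comes from a seeded nonparametric bootstrap
#' with percentile confidence intervals.
#'
#' @param data Tibble holding every indicator column; no missing values.
#' @param spec An `emnet_plspm_spec`.
#' @param seed Integer seed for the bootstrap.
#' @param boot Bootstrap resamples (0 skips the bootstrap).
#' @param tol,max_iter Convergence tolerance and iteration cap.
#' @param scheme Inner weighting scheme: `"path"`, `"centroid"`, or
#'   `"factorial"`.
#' @param boot_p `"percentile"` (default) or `"normal"` p-values for
#'   paths.
#' @return A list with class `"emnet_plspm"`: `weights` (indicator-level
#'   weight/loading/communality), `paths` (with bootstrap se/CI/p when
#'   `boot > 0`), `r_squared`, `gof`, `effects` (direct/indirect/total),
#'   `scores`, `inner`, `iterations`, `converged`.
#' @export
fit_plspm <- function(data, spec, seed = 1L, boot = 500L,
                      tol = 1e-7, max_iter = 300L,
                      scheme = c("path", "centroid", "factorial"),
                      boot_p = c("percentile", "normal")) {
  scheme <- match.arg(scheme)
  boot_p <- match.arg(boot_p)
  stopifnot(inherits(spec, "emnet_plspm_spec"))
  ind <- unlist(spec$blocks, use.names = FALSE)
  missing_ind <- setdiff(ind, names(data))
  if (length(missing_ind)) {
    abort(paste0("indicator column(s) absent from data: ",
                 paste(missing_ind, collapse = ", ")))
  }
  X <- as.matrix(data[ind])
  if (anyNA(X)) abort("missing values are not supported; complete the data first")
  const <- ind[apply(X, 2, sd) == 0]
  if (length(const)) {
    abort(paste0("constant indicator(s): ", paste(const, collapse = ", ")))
  }
  n <- nrow(X)
  biggest <- max(lengths(spec$blocks))
  if (n <= biggest) {
    warn("sample size does not exceed the largest block; estimates will be unstable")
  }
  core <- plspm_core(X, spec, tol = tol, max_iter = max_iter, scheme = scheme)
  if (!core$converged) {
    abort(paste0("PLS-PM did not converge in ", max_iter,
                 " iterations (last weight change ", format(core$last_delta), ")"))
  }

  paths_tbl <- core$paths
  if (boot > 0) {
    set.seed(seed)
    bmat <- matrix(NA_real_, boot, nrow(paths_tbl))
    for (b in seq_len(boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      bres <- tryCatch(
        plspm_core(X[idx, , drop = FALSE], spec, tol = tol,
                   max_iter = max_iter, scheme = scheme),
        error = identity
      )
      if (!inherits(bres, "error") && bres$converged) {
        bmat[b, ] <- bres$paths$estimate
      }
    }
    ok <- colSums(!is.na(bmat)) > 0
    paths_tbl$boot_se <- apply(bmat, 2, sd, na.rm = TRUE)
    paths_tbl$ci_lo <- apply(bmat, 2, quantile, 0.025, na.rm = TRUE)
    paths_tbl$ci_hi <- apply(bmat, 2, quantile, 0.975, na.rm = TRUE)
    paths_tbl$p_value <- vapply(seq_len(nrow(paths_tbl)), function(i) {
      if (!ok[i]) return(NA_real_)
      if (boot_p == "normal") {
        2 * pnorm(-abs(paths_tbl$estimate[i] / paths_tbl$boot_se[i]))
      } else {
        b <- bmat[, i][!is.na(bmat[, i])]
        min(1, 2 * min(mean(b <= 0), mean(b >= 0)) + 2 / (length(b) + 1))
      }
    }, numeric(1))
  }

  structure(
    c(core[c("weights", "r_squared", "gof", "scores", "inner",
             "iterations", "converged")],
      list(paths = paths_tbl,
           effects = effects_from_matrix(core$B),
           spec = spec, seed = seed, boot = boot, scheme = scheme)),
    class = "emnet_plspm"
  )
}

# one PLS-PM estimation pass on a raw indicator matrix
plspm_core <- function(X, spec, tol, max_iter, scheme) {
  blocks <- spec$blocks
  lat <- names(blocks)
  inner <- spec$inner[lat, lat]
  Xs <- scale(X)
  idx <- lapply(blocks, function(b) match(b, colnames(X)))
  w <- lapply(idx, function(i) {
    wi <- rep(1, length(i))
    wi / sd_vec(Xs[, i, drop = FALSE] %*% wi)
  })
  neighbors <- inner | t(inner)
  latent_scores <- function(w) {
    Y <- vapply(seq_along(idx), function(j) {
      as.numeric(Xs[, idx[[j]], drop = FALSE] %*% w[[j]])
    }, numeric(nrow(Xs)))
    colnames(Y) <- lat
    scale(Y)
  }
  it <- 0L
  delta <- Inf
  Y <- latent_scores(w)
  while (it < max_iter && delta >= tol) {
    it <- it + 1L
    E <- matrix(0, length(lat), length(lat), dimnames = list(lat, lat))
    for (j in lat) {
      nb <- lat[neighbors[, j]]
      if (!length(nb)) next
      preds <- lat[inner[, j]]
      succs <- lat[inner[j, ]]
      if (scheme == "path") {
        if (length(preds)) {
          E[preds, j] <- coef(lm.fit(cbind(1, Y[, preds, drop = FALSE]),
                                     Y[, j]))[-1]
        }
        if (length(succs)) E[succs, j] <- cor(Y[, succs, drop = FALSE], Y[, j])
      } else if (scheme == "centroid") {
        E[nb, j] <- sign(cor(Y[, nb, drop = FALSE], Y[, j]))
      } else {
        E[nb, j] <- cor(Y[, nb, drop = FALSE], Y[, j])
      }
    }
    Z <- Y %*% E
    w_new <- lapply(seq_along(idx), function(j) {
      z <- Z[, j]
      if (all(z == 0)) return(w[[j]]) # isolated latent: keep weights
      wi <- as.numeric(crossprod(Xs[, idx[[j]], drop = FALSE], z)) / (nrow(Xs) - 1)
      if (sum(wi) < 0) wi <- -wi # orient with the indicator majority
      wi / sd_vec(Xs[, idx[[j]], drop = FALSE] %*% wi)
    })
    delta <- max(abs(unlist(w_new) - unlist(w)))
    w <- w_new
    Y <- latent_scores(w)
  }

  loadings <- unlist(lapply(seq_along(idx), function(j) {
    cor(X[, idx[[j]], drop = FALSE], Y[, j])
  }))
  weights_tbl <- tibble::tibble(
    block = rep(lat, lengths(idx)),
    indicator = unlist(blocks, use.names = FALSE),
    weight = unlist(w),
    loading = as.numeric(loadings),
    communality = as.numeric(loadings)^2
  )

  B <- matrix(0, length(lat), length(lat), dimnames = list(lat, lat))
  r2 <- setNames(rep(NA_real_, length(lat)), lat)
  for (j in lat) {
    preds <- lat[inner[, j]]
    if (!length(preds)) next
    fit <- lm.fit(cbind(1, Y[, preds, drop = FALSE]), Y[, j])
    B[preds, j] <- coef(fit)[-1]
    r2[j] <- 1 - sum(fit$residuals^2) / sum((Y[, j] - mean(Y[, j]))^2)
  }
  endo <- lat[colSums(inner) > 0]
  multi <- weights_tbl$block %in% lat[lengths(blocks) > 1]
  comm_pool <- if (any(multi)) weights_tbl$communality[multi] else
    weights_tbl$communality
  gof <- sqrt(mean(comm_pool) * mean(r2[endo]))

  paths <- which(inner, arr.ind = TRUE)
  list(
    weights = weights_tbl,
    paths = tibble::tibble(
      from = lat[paths[, 1]], to = lat[paths[, 2]],
      estimate = B[paths]
    ),
    B = B,
    r_squared = tibble::tibble(latent = endo, r_squared = unname(r2[endo])),
    gof = gof,
    scores = tibble::as_tibble(cbind(
      tibble::tibble(sample = rownames(X) %||% paste0("s", seq_len(nrow(X)))),
      as.data.frame(Y)
    )),
    inner = inner,
    iterations = it,
    converged = delta < tol,
    last_delta = delta
  )
}

sd_vec <- function(x) sd(as.numeric(x))

#' Direct, indirect and total effects between latent variables
#'
#' The indirect effect of one latent on another is the sum over all
#' directed paths (of length two or more) of the products of the path
#' coefficients along each path; the total effect adds the direct edge.
#'
#' @param result A fitted `emnet_plspm`.
#' @return Tibble: `from`, `to`, `direct`, `indirect`, `total` for every
#'   ordered latent pair connected by at least one path.
#' @export
effects_decomposition <- function(result) {
  stopifnot(inherits(result, "emnet_plspm"))
  result$effects
}

effects_from_matrix <- function(B) {
  lat <- rownames(B)
  total <- matrix(0, nrow(B), ncol(B), dimnames = dimnames(B))
  P <- B
  for (k in seq_len(nrow(B))) { # B is nilpotent (acyclic), series terminates
    total <- total + P
    P <- P %*% B
  }
  idx <- which(total != 0 | B != 0, arr.ind = TRUE)
  tibble::tibble(
    from = lat[idx[, 1]], to = lat[idx[, 2]],
    direct = B[idx], indirect = total[idx] - B[idx], total = total[idx]
  )
}

#' @export
print.emnet_plspm <- function(x, ...) {
  cat(sprintf("<emnet_plspm> %d latents, GoF = %.3f (%d iterations)\n",
              ncol(x$inner), x$gof, x$iterations))
  print(as.data.frame(x$paths), row.names = FALSE, digits = 3)
  invisible(x)
}
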