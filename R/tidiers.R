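#' Tidy and glance methods for emnet result objects
#'
#' Broom-style accessors: `tidy()` returns the per-term / per-edge /
#' per-group tibble of an object, `glance()` its one-row model summary.
#'
#' @param x An emnet result object.
#' @param ... Unused.
#' @return A tibble.
#' @name emnet-tidiers
NULL

#' @rdname emnet-tidiers
#' @export
tidy.emnet_network <- function(x, ...) {
  if (igraph::ecount(x$graph) == 0L) {
    return(tibble::tibble(from = character(), to = character(),
                          rho = double(), p = double(), sign = integer()))
  }
  el <- igraph::as_data_frame(x$graph, what = "edges")
  tibble::as_tibble(el)
}

#' @rdname emnet-tidiers
#' @export
glance.emnet_network <- function(x, ...) {
  tibble::as_tibble(network_topology(x))
}

#' @rdname emnet-tidiers
#' @export
tidy.emnet_plspm <- function(x, ...) x$paths

#' @rdname emnet-tidiers
#' @export
glance.emnet_plspm <- function(x, ...) {
  tibble::tibble(
    gof = x$gof,
    mean_r_squared = mean(x$r_squared$r_squared),
    n_latents = ncol(x$inner),
    n_paths = nrow(x$paths),
    iterations = x$iterations,
    converged = x$converged
  )
}

#' @rdname emnet-tidiers
#' @export
tidy.emnet_lmm <- function(x, ...) x$fixed

#' @rdname emnet-tidiers
#' @export
glance.emnet_lmm <- function(x, ...) {
  tibble::tibble(
    var_site = x$varcomp$variance[x$varcomp$component == "site"],
    var_residual = x$varcomp$variance[x$varcomp$component == "residual"],
    singular = x$flags$singular,
    refit_ml = x$flags$refit_ml,
    env = x$env
  )
}

#' @rdname emnet-tidiers
#' @export
tidy.emnet_duncan <- function(x, ...) x$groups

#' @rdname emnet-tidiers
#' @export
glance.emnet_duncan <- function(x, ...) x$anova

#' @rdname emnet-tidiers
#' @export
tidy.emnet_rf <- function(x, ...) x$importance

#' @rdname emnet-tidiers
#' @export
glance.emnet_rf <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, p_value = x$p_value,
                 n = x$n, low_n = x$low_n)
}

#' @rdname emnet-tidiers
#' @export
tidy.emnet_beta <- function(x, ...) {
  pairs <- which(upper.tri(x$beta_sor), arr.ind = TRUE)
  ids <- rownames(x$beta_sor)
  tibble::tibble(
    sample_a = ids[pairs[, 1]], sample_b = ids[pairs[, 2]],
    beta_sor = x$beta_sor[pairs], beta_sim = x$beta_sim[pairs],
    beta_sne = x$beta_sne[pairs]
  )
}

#' @rdname emnet-tidiers
#' @export
glance.emnet_beta <- function(x, ...) x$multi_site

#' @export
print.emnet_duncan <- function(x, ...) {
  cat(sprintf("<emnet_duncan> F = %.3f, p = %.4g\n",
              x$anova$f_statistic, x$anova$p_value))
  print(as.data.frame(x$groups), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
print.emnet_collinearity <- function(x, ...) {
  cat("<emnet_collinearity> retained:", paste(x$retained, collapse = ", "), "\n")
  if (nrow(x$dropped)) {
    cat("dropped:\n")
    print(as.data.frame(x$dropped), row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @export
print.emnet_lmm <- function(x, ...) {
  cat(sprintf("<emnet_lmm> %s ~ %s * %s + (1|%s)%s\n",
              x$response, x$plant, x$env, x$site,
              if (x$flags$singular) "  [singular site variance]" else ""))
  print(as.data.frame(x$fixed), row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
print.emnet_rf <- function(x, ...) {
  cat(sprintf("<emnet_rf> OOB R^2 = %.3f, permutation p = %.4g (n = %d)\n",
              x$r_squared, x$p_value, x$n))
  print(as.data.frame(x$importance), row.names = FALSE, digits = 3)
  invisible(x)
}
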