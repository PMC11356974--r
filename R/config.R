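#' Run configuration for the EM fungal network pipeline
#'
#' Bundles every threshold the pipeline applies, so a whole analysis is
#' reproducible from one object. Defaults follow common practice for
#' amplicon co-occurrence studies: taxa are kept when their overall relative
#' abundance is at least 0.01%; edges within the fungal network require
#' \eqn{|\rho| \ge 0.6} at \eqn{p \le 0.001}; edges in the joint
#' fungus-bacteria (cross-kingdom) network require \eqn{|\rho| \ge 0.6} at
#' \eqn{p \le 0.05}; node roles use the classical Zi/Pi cut-offs 2.5 and
#' 0.62; covariates are screened at \eqn{|r| < 0.6}; a PLS path model is
#' considered acceptable at GoF > 0.5.
#'
#' @param seed Integer seed driving every stochastic step.
#' @param abundance_filter Minimum overall relative abundance for a taxon to
#'   enter correlation analysis (fraction of the grand total).
#' @param fungal_edge_r,fungal_edge_p Correlation and p-value cut-offs for
#'   the single-kingdom (EM fungal) network.
#' @param crosskingdom_edge_r,crosskingdom_edge_p Cut-offs for the joint
#'   fungal + bacterial network.
#' @param zi_cut,pi_cut Role-classification thresholds for within-module
#'   degree z-score (Zi) and participation coefficient (Pi).
#' @param collinearity_cut Pairwise-|r| threshold above which covariates are
#'   greedily eliminated before modelling.
#' @param gof_accept Goodness-of-fit acceptance level for PLS path models.
#' @param bootstrap_n Bootstrap resamples for PLS-PM path inference.
#'
#' @return A list with class `"emnet_config"`.
#' @examples
#' cfg <- emnet_config(seed = 1)
#' cfg$fungal_edge_p
#' @export
emnet_config <- function(seed = 1L,
                         abundance_filter = 1e-4,
                         fungal_edge_r = 0.6,
                         fungal_edge_p = 0.001,
                         crosskingdom_edge_r = 0.6,
                         crosskingdom_edge_p = 0.05,
                         zi_cut = 2.5,
                         pi_cut = 0.62,
                         collinearity_cut = 0.6,
                         gof_accept = 0.5,
                         bootstrap_n = 500L) {
  stopifnot(
    is.numeric(seed), length(seed) == 1L,
    abundance_filter >= 0, abundance_filter < 1,
    fungal_edge_r >= 0, fungal_edge_r <= 1,
    fungal_edge_p >= 0, fungal_edge_p <= 1,
    crosskingdom_edge_r >= 0, crosskingdom_edge_r <= 1,
    crosskingdom_edge_p >= 0, crosskingdom_edge_p <= 1,
    zi_cut >= 0, pi_cut >= 0, pi_cut <= 1,
    collinearity_cut >= 0, collinearity_cut <= 1,
    gof_accept >= 0, gof_accept <= 1,
    bootstrap_n >= 0
  )
  structure(
    list(
      seed = as.integer(seed),
      abundance_filter = abundance_filter,
      fungal_edge_r = fungal_edge_r,
      fungal_edge_p = fungal_edge_p,
      crosskingdom_edge_r = crosskingdom_edge_r,
      crosskingdom_edge_p = crosskingdom_edge_p,
      zi_cut = zi_cut,
      pi_cut = pi_cut,
      collinearity_cut = collinearity_cut,
      gof_accept = gof_accept,
      bootstrap_n = as.integer(bootstrap_n)
    ),
    class = "emnet_config"
  )
}

#' @export
print.emnet_config <- function(x, ...) {
  cat("<emnet_config>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
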