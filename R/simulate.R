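#' Parameters for the synthetic study generator
#'
#' Describes a study of 18 composite samples — six plots in each of three
#' forest types (pure oak `PF`, oak-pine mixture `QPF`, oak-broadleaf
#' mixture `QBF`) — with known, configurable coupling between neighboring
#' plant richness, soil/litter covariates, the rhizosphere bacterial
#' community, and the EM fungal community of the focal trees.
#'
#' The generative model, per sample \eqn{i} in site \eqn{s}:
#' \itemize{
#'   \item plant richness \eqn{R_i \sim} Poisson around its forest-type
#'     mean, truncated at 1;
#'   \item latent log EM pool size
#'     \eqn{\log S_i = \log S_0 + \beta (\log R_i - \overline{\log R}) +
#'     u_s + \varepsilon_i}, with site intercepts
#'     \eqn{u_s \sim N(0, \sigma_{site}^2)} and noise
#'     \eqn{\varepsilon_i \sim N(0, \sigma^2)}; `coupling_beta` is the
#'     elasticity of EM diversity with respect to plant richness and
#'     `coupling_beta = 0` is the null model;
#'   \item the realized EM taxa are drawn from a ranked species pool with
#'     decaying inclusion weights (a shared core plus sample-specific
#'     tail), relative abundances from a symmetric Dirichlet, and counts
#'     from a multinomial at `sequencing_depth` reads;
#'   \item bacterial taxa are generated in planted co-occurrence modules:
#'     taxa within a block share a Gaussian latent factor (correlation
#'     `block_rho`), the first block's factor is tied to plant richness
#'     with weight `bact_richness_coupling`, and latent scores map
#'     monotonically to counts — so network inference has ground truth;
#'   \item each covariate in `env_effect` is drawn with the stated
#'     correlation to standardized plant richness through a shared latent
#'     habitat factor.
#' }
#'
#' @param n_sites_per_type Plots per forest type (the study design uses 6).
#' @param forest_types Forest-type labels.
#' @param richness_means Named mean plant richness per forest type
#'   (species per plot).
#' @param pool_size_fungi,pool_size_bacteria Species-pool sizes.
#' @param coupling_beta Slope of log EM diversity on log plant richness.
#' @param env_effect Named vector of covariate-richness correlations.
#' @param sequencing_depth Reads per composite sample.
#' @param dirichlet_concentration Symmetric Dirichlet concentration for
#'   fungal relative abundances (smaller = more uneven).
#' @param network_block_sizes Sizes of the planted bacterial co-occurrence
#'   modules.
#' @param block_rho Within-module latent correlation of planted blocks.
#' @param bact_richness_coupling Correlation between the first bacterial
#'   module factor and plant richness.
#' @param em_base_richness EM pool size \eqn{S_0} at average plant richness.
#' @param site_sd,noise_sd Site-intercept and residual SD of log EM pool
#'   size.
#' @param seed Integer seed; a fixed seed yields an identical dataset.
#'
#' @return A list with class `"emnet_sim_params"`.
#' @seealso [simulate_dataset()]
#' @export
sim_params <- function(n_sites_per_type = 6L,
                       forest_types = c("PF", "QPF", "QBF"),
                       richness_means = c(PF = 15, QPF = 24, QBF = 30),
                       pool_size_fungi = 300L,
                       pool_size_bacteria = 400L,
                       coupling_beta = 0.5,
                       env_effect = c(SOC = 0.6, TN = 0.5, LC = 0.4, LP = 0.3,
                                      pH = -0.2, NH4 = 0.1, NO3 = 0.1, SAP = 0),
                       sequencing_depth = 10000L,
                       dirichlet_concentration = 1,
                       network_block_sizes = c(25L, 20L, 15L),
                       block_rho = 0.7,
                       bact_richness_coupling = 0.3,
                       em_base_richness = 40,
                       site_sd = 0.1,
                       noise_sd = 0.2,
                       seed = 1L) {
  if (any(richness_means <= 0)) abort("richness means must be positive")
  stopifnot(
    n_sites_per_type >= 1, pool_size_fungi >= 1, pool_size_bacteria >= 1,
    sequencing_depth >= 1, dirichlet_concentration > 0,
    all(network_block_sizes >= 1), block_rho >= 0, block_rho < 1,
    em_base_richness >= 1, site_sd >= 0, noise_sd >= 0
  )
  if (is.null(names(richness_means))) names(richness_means) <- forest_types
  if (!all(forest_types %in% names(richness_means))) {
    abort("richness_means must name every forest type")
  }
  structure(
    list(
      n_sites_per_type = as.integer(n_sites_per_type),
      forest_types = forest_types,
      richness_means = richness_means,
      pool_size_fungi = as.integer(pool_size_fungi),
      pool_size_bacteria = as.integer(pool_size_bacteria),
      coupling_beta = coupling_beta,
      env_effect = env_effect,
      sequencing_depth = as.integer(sequencing_depth),
      dirichlet_concentration = dirichlet_concentration,
      network_block_sizes = as.integer(network_block_sizes),
      block_rho = block_rho,
      bact_richness_coupling = bact_richness_coupling,
      em_base_richness = em_base_richness,
      site_sd = site_sd,
      noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "emnet_sim_params"
  )
}

#' Generate a study-shaped synthetic dataset
#'
#' Draws one complete dataset — EM fungal count table, bacterial count
#' table, and per-sample metadata — under the generative model described in
#' [sim_params()], and returns the generating truth alongside so parameter
#' recovery is measurable downstream.
#'
#' @param p An `emnet_sim_params` object.
#' @return A list with class `"emnet_sim"`: `fungal_table`,
#'   `bacterial_table` (abundance tibbles), `metadata` (sample, site,
#'   forest_type, plant_richness, covariates), and `truth` (per-sample
#'   latent log diversity, realized pool sizes, site effects, planted
#'   bacterial module membership, and the generating parameters).
#' @examples
#' sim <- simulate_dataset(sim_params(seed = 7))
#' dim(sim$fungal_table)
#' @export
simulate_dataset <- function(p = sim_params()) {
  stopifnot(inherits(p, "emnet_sim_params"))
  set.seed(p$seed)
  types <- rep(p$forest_types, each = p$n_sites_per_type)
  site <- rep(paste0("site", seq_len(p$n_sites_per_type)), times = length(p$forest_types))
  samples <- paste(types, rep(seq_len(p$n_sites_per_type), length(p$forest_types)),
                   sep = "_")
  n <- length(samples)

  richness <- pmax(1L, rpois(n, p$richness_means[types]))
  site_eff <- setNames(rnorm(p$n_sites_per_type, 0, p$site_sd),
                       unique(site))

  log_r <- log(richness)
  lat <- log(p$em_base_richness) +
    p$coupling_beta * (log_r - mean(log_r)) +
    site_eff[site] + rnorm(n, 0, p$noise_sd)
  pool_n <- pmin(pmax(3L, as.integer(round(exp(lat)))), p$pool_size_fungi)
  if (any(pool_n > p$sequencing_depth)) {
    warn("sequencing depth below realized pool size; richness will saturate")
  }

  # ranked pool with decaying inclusion weights: shared core + variable tail
  incl_w <- seq_len(p$pool_size_fungi)^-0.8
  fungal <- matrix(0L, n, p$pool_size_fungi,
                   dimnames = list(samples, sprintf("F%03d", seq_len(p$pool_size_fungi))))
  for (i in seq_len(n)) {
    taxa <- sample.int(p$pool_size_fungi, pool_n[i], prob = incl_w)
    rel <- rgamma(pool_n[i], shape = p$dirichlet_concentration)
    fungal[i, taxa] <- rmultinom(1L, p$sequencing_depth, rel / sum(rel))[, 1L]
  }

  # planted bacterial modules through a Gaussian copula
  membership <- planted_partition_truth(p)
  z_rich <- as.numeric(scale(log_r))
  n_block <- length(p$network_block_sizes)
  factors <- matrix(rnorm(n * n_block), n, n_block)
  if (n_block >= 1) {
    bc <- p$bact_richness_coupling
    factors[, 1] <- bc * z_rich + sqrt(1 - bc^2) * factors[, 1]
  }
  bact_lat <- matrix(rnorm(n * p$pool_size_bacteria), n, p$pool_size_bacteria)
  planted <- which(membership > 0)
  for (j in planted) {
    f <- factors[, membership[j]]
    bact_lat[, j] <- sqrt(p$block_rho) * f + sqrt(1 - p$block_rho) * bact_lat[, j]
  }
  base_mu <- rnorm(p$pool_size_bacteria, 0, 1)
  bacterial <- matrix(0L, n, p$pool_size_bacteria,
                      dimnames = list(samples, sprintf("B%03d", seq_len(p$pool_size_bacteria))))
  for (i in seq_len(n)) {
    wt <- exp(base_mu + 1.5 * bact_lat[i, ])
    bacterial[i, ] <- rmultinom(1L, p$sequencing_depth, wt / sum(wt))[, 1L]
  }

  # covariates with stated correlation to standardized plant richness
  cov_scale <- c(SOC = 5, TN = 0.4, LC = 40, LP = 0.3, pH = 0.3,
                 NH4 = 2, NO3 = 3, SAP = 2)
  cov_mean <- c(SOC = 20, TN = 1.5, LC = 420, LP = 1.2, pH = 7.2,
                NH4 = 8, NO3 = 10, SAP = 6)
  env <- purrr::imap(p$env_effect, function(e, nm) {
    x <- e * z_rich + sqrt(max(0, 1 - e^2)) * rnorm(n)
    (cov_mean[nm] %||% 0) + (cov_scale[nm] %||% 1) * x
  })

  metadata <- tibble::tibble(
    sample = samples, site = site, forest_type = types,
    plant_richness = as.integer(richness), !!!env
  )

  structure(
    list(
      fungal_table = tibble::as_tibble(fungal, rownames = "sample"),
      bacterial_table = tibble::as_tibble(bacterial, rownames = "sample"),
      metadata = metadata,
      truth = list(
        latent_log_diversity = setNames(lat, samples),
        realized_pool = setNames(pool_n, samples),
        plant_richness = setNames(richness, samples),
        site_effects = site_eff,
        bacterial_modules = membership,
        params = p
      )
    ),
    class = "emnet_sim"
  )
}

#' Ground-truth module membership of the planted bacterial blocks
#'
#' @param p An `emnet_sim_params` object.
#' @return Integer vector over bacterial taxa: module id for planted taxa
#'   (consecutive blocks in taxon order), 0 for unplanted background taxa.
#' @examples
#' table(planted_partition_truth(sim_params(network_block_sizes = c(5, 5))))
#' @export
planted_partition_truth <- function(p) {
  stopifnot(inherits(p, "emnet_sim_params"))
  sizes <- p$network_block_sizes
  if (sum(sizes) > p$pool_size_bacteria) {
    abort("planted blocks exceed the bacterial pool size")
  }
  mem <- integer(p$pool_size_bacteria)
  mem[seq_len(sum(sizes))] <- rep(seq_along(sizes), sizes)
  names(mem) <- sprintf("B%03d", seq_len(p$pool_size_bacteria))
  mem
}

#' Generate a two-block count table with bridge taxa
#'
#' A focused generator for validating network inference and node-role
#' classification: two planted modules whose taxa share a block-specific
#' Gaussian factor, a group of bridge taxa loading equally on both block
#' factors, and independent background taxa. Counts are Poisson draws on
#' absolute latent abundances (no compositional closure), so the observed
#' rank correlations track the planted latent correlations and edge
#' detection can be judged against clean ground truth.
#'
#' Note the structural bound this fixture exposes: if module detection
#' recovers exactly the two planted blocks, a bridge node's participation
#' coefficient cannot exceed \eqn{1 - 1/2 = 0.5}, below the conventional
#' 0.62 connector threshold — connectors require edges spread over at
#' least three modules.
#'
#' @param n_samples Number of samples (rows).
#' @param block_sizes Two (or more) planted block sizes.
#' @param n_bridge Number of bridge taxa.
#' @param n_noise Number of independent background taxa.
#' @param within_rho Within-block latent correlation.
#' @param bridge_loading Loading of each bridge taxon on each of the first
#'   two block factors (capped so the latent variance stays 1).
#' @param base_count Expected count at latent 0.
#' @param seed Integer seed.
#' @return List: `table` (abundance tibble) and `membership` (character
#'   vector over taxa: `"block<k>"`, `"bridge"`, `"noise"`).
#' @export
simulate_planted_blocks <- function(n_samples = 18L,
                                    block_sizes = c(8L, 6L),
                                    n_bridge = 4L,
                                    n_noise = 12L,
                                    within_rho = 0.95,
                                    bridge_loading = 0.7,
                                    base_count = 200,
                                    seed = 1L) {
  stopifnot(length(block_sizes) >= 2, within_rho > 0, within_rho < 1,
            2 * bridge_loading^2 <= 1)
  set.seed(seed)
  n_taxa <- sum(block_sizes) + n_bridge + n_noise
  membership <- c(
    rep(paste0("block", seq_along(block_sizes)), block_sizes),
    rep("bridge", n_bridge), rep("noise", n_noise)
  )
  factors <- matrix(rnorm(n_samples * length(block_sizes)), n_samples)
  lat <- matrix(rnorm(n_samples * n_taxa), n_samples, n_taxa)
  for (j in which(startsWith(membership, "block"))) {
    f <- factors[, as.integer(sub("block", "", membership[j]))]
    lat[, j] <- sqrt(within_rho) * f + sqrt(1 - within_rho) * lat[, j]
  }
  a <- bridge_loading
  res_sd <- sqrt(1 - 2 * a^2)
  for (j in which(membership == "bridge")) {
    lat[, j] <- a * factors[, 1] + a * factors[, 2] + res_sd * lat[, j]
  }
  counts <- matrix(
    rpois(n_samples * n_taxa, as.vector(base_count * exp(1.2 * lat))),
    n_samples, n_taxa,
    dimnames = list(paste0("s", seq_len(n_samples)),
                    sprintf("T%03d", seq_len(n_taxa)))
  )
  list(
    table = tibble::as_tibble(counts, rownames = "sample"),
    membership = setNames(membership, colnames(counts))
  )
}

#' @export
print.emnet_sim <- function(x, ...) {
  cat(sprintf(
    "<emnet_sim> %d samples; %d fungal taxa, %d bacterial taxa; coupling_beta = %g\n",
    nrow(x$metadata), ncol(x$fungal_table) - 1L, ncol(x$bacterial_table) - 1L,
    x$truth$params$coupling_beta
  ))
  invisible(x)
}
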