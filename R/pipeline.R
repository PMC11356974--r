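#' Full per-sample topology of induced subnetworks
#'
#' Extends [sample_subnetworks()] with the whole metric panel of
#' [network_topology()] per sample — average degree, average distance,
#' density, assortativity, degree/eigenvector centrality — which supplies
#' the per-sample "biotic factor" indicators of the cross-kingdom
#' network.
#'
#' @inheritParams sample_subnetworks
#' @return Tibble: `sample` plus every [network_topology()] column.
#' @export
sample_subnetwork_topology <- function(net, table) {
  stopifnot(inherits(net, "emnet_network"))
  m <- abundance_matrix(table)
  nodes <- igraph::V(net$graph)$name
  purrr::map_dfr(rownames(m), function(s) {
    present <- intersect(nodes, colnames(m)[m[s, ] > 0])
    sg <- igraph::induced_subgraph(net$graph, present)
    sub <- new_emnet_network(sg, params = net$params,
                             provenance = paste0(net$provenance, ":", s))
    dplyr::bind_cols(tibble::tibble(sample = s), network_topology(sub))
  })
}

#' Run the whole analysis pipeline on a synthetic dataset
#'
#' Simulates a study-shaped dataset and drives every stage over it:
#' alpha/beta diversity, per-forest-type EM fungal networks with
#' per-sample subnetworks and the multi-complexity index, Zi-Pi roles and
#' keystone correlations on the all-sample fungal network, a
#' cross-kingdom (fungal + bacterial) network supplying per-sample biotic
#' factors, response ratios of the mixtures against the pure forest,
#' diversity regressions, ANOVA + Duncan letters, collinearity screening,
#' interaction mixed models, random-forest contributions, and the PLS
#' path model. All result tables are written as TSV (networks as GraphML,
#' scalars as JSON) under `out_dir`; with a fixed seed the output files
#' are byte-identical across runs.
#'
#' @param seed Integer seed for the whole run.
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param params Simulation parameters; seed is overridden by `seed`.
#' @param config An [emnet_config()]; seed is overridden by `seed`.
#' @param rf_perms Response permutations for the random-forest test.
#' @return Invisibly, a list with class `"emnet_run"` holding every
#'   intermediate result.
#' @export
run_emnet_pipeline <- function(seed = 1L, out_dir = NULL,
                               params = sim_params(),
                               config = emnet_config(),
                               rf_perms = 499L) {
  params$seed <- as.integer(seed)
  config$seed <- as.integer(seed)
  sim <- simulate_dataset(params)
  fungal <- sim$fungal_table
  meta <- sim$metadata

  alpha <- alpha_diversity(fungal)
  beta <- beta_partition(fungal)

  # per-forest-type fungal networks and their per-sample subnetworks
  types <- unique(meta$forest_type)
  nets <- purrr::map(setNames(types, types), function(ft) {
    sub <- fungal[fungal$sample %in% meta$sample[meta$forest_type == ft], ]
    filt <- filter_by_relative_abundance(sub, config$abundance_filter)
    suppressWarnings(build_network(
      filt, r_cut = config$fungal_edge_r, p_cut = config$fungal_edge_p,
      provenance = paste0("fungal:", ft)
    ))
  })
  topo <- purrr::imap_dfr(nets, function(nt, ft) {
    dplyr::bind_cols(tibble::tibble(forest_type = ft), network_topology(nt))
  })
  subnet <- purrr::imap_dfr(nets, function(nt, ft) {
    sub <- fungal[fungal$sample %in% meta$sample[meta$forest_type == ft], ]
    sample_subnetworks(nt, sub)
  })
  subnet <- subnet[match(meta$sample, subnet$sample), ]
  subnet <- multi_net(subnet) # standardized across all samples, pooled

  # all-sample fungal network for node roles and keystones
  fungal_filt <- filter_by_relative_abundance(fungal, config$abundance_filter)
  net_all <- suppressWarnings(build_network(
    fungal_filt, r_cut = config$fungal_edge_r, p_cut = config$fungal_edge_p,
    provenance = "fungal:all"
  ))
  roles <- zi_pi(net_all, seed = seed, zi_cut = config$zi_cut,
                 pi_cut = config$pi_cut)

  # cross-kingdom network: concatenated fungal + bacterial taxa
  joint <- dplyr::inner_join(fungal_filt,
                             filter_by_relative_abundance(
                               sim$bacterial_table, config$abundance_filter),
                             by = "sample")
  net_ck <- suppressWarnings(build_network(
    joint, r_cut = config$crosskingdom_edge_r,
    p_cut = config$crosskingdom_edge_p, provenance = "cross-kingdom:all"
  ))
  biotic <- sample_subnetwork_topology(net_ck, joint)
  biotic <- dplyr::transmute(
    biotic, sample = .data$sample,
    Vnum = .data$node_num, Edgnum = .data$edge_num,
    AD = .data$average_degree, Avgdist = .data$average_distance,
    Den = .data$density, Assort = .data$assortativity,
    Cenbet = .data$betweenness_centrality, Cendeg = .data$degree_centrality,
    Ceneig = .data$eigenvector_centrality
  )
  biotic <- dplyr::mutate(biotic, dplyr::across(
    dplyr::where(is.numeric),
    ~ ifelse(is.na(.x), mean(.x, na.rm = TRUE), .x)
  ))

  # per-sample indicator table shared by several stages
  div <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(alpha), -"depth"), beta$summary,
    by = "sample"
  )
  div <- dplyr::inner_join(div, tibble::as_tibble(subnet), by = "sample")

  rr_data <- dplyr::inner_join(meta[c("sample", "forest_type")], div,
                               by = "sample")
  rr_pos <- dplyr::select(
    rr_data, -"multi_net" # spans 0; lnR needs positive means
  )
  respratio <- response_ratios(rr_pos, group_col = "forest_type",
                               control = "PF")

  regressions <- suppressWarnings(fit_diversity_regressions(div, meta))
  duncan <- purrr::map(
    setNames(names(div)[-1], names(div)[-1]),
    function(v) anova_duncan(rr_data[[v]], rr_data$forest_type)
  )
  anova_tbl <- purrr::imap_dfr(duncan, function(d, v) {
    dplyr::bind_cols(tibble::tibble(metric = v), d$anova)
  })

  env_cols <- intersect(c("SOC", "TN", "LC", "LP", "pH", "NH4", "NO3", "SAP"),
                        names(meta))
  screen <- collinearity_filter(meta[env_cols], cut = config$collinearity_cut)
  lmm_data <- dplyr::inner_join(meta, div, by = "sample")
  lmm_data$log_richness <- log(lmm_data$richness)
  lmm_data$log_plant <- log(lmm_data$plant_richness)
  lmms <- purrr::map(setNames(screen$retained, screen$retained), function(ev) {
    fit_interaction_lmm(lmm_data, response = "log_richness", env = ev,
                        plant = "log_plant", site = "site")
  })
  lmm_tbl <- purrr::imap_dfr(lmms, function(f, ev) {
    dplyr::bind_cols(tibble::tibble(env = ev), f$fixed)
  })

  rf_data <- dplyr::inner_join(lmm_data, biotic, by = "sample")
  abiotic_set <- intersect(c("SOC", "TN", "LC", "LP"), screen$retained)
  rf_abiotic <- suppressWarnings(rf_contributions(
    rf_data, "log_richness", abiotic_set, n_perm = rf_perms, seed = seed
  ))
  rf_biotic <- suppressWarnings(rf_contributions(
    rf_data, "log_richness", c("Assort", "Avgdist", "Ceneig"),
    n_perm = rf_perms, seed = seed
  ))

  bray <- as.matrix(vegan::vegdist(abundance_matrix(fungal), method = "bray"))
  axes <- pca_axes(bray, k = 2)
  ind <- dplyr::inner_join(meta, div, by = "sample")
  ind <- dplyr::inner_join(ind, axes, by = "sample")
  ind <- dplyr::inner_join(ind, biotic, by = "sample")
  blocks <- list(
    plant = "plant_richness",
    abiotic = c("SOC", "TN", "LC", "LP"),
    biotic = c("Assort", "Avgdist", "Ceneig"),
    em_diversity = c("richness", "shannon", "simpson", "chao1", "ace",
                     "axis1", "axis2", "node_num", "edge_num",
                     "betweenness_centrality", "multi_net")
  )
  # constant indicators (e.g. a subnetwork metric degenerate at this
  # sparsity) carry no information and are dropped from the measurement model
  constant_ind <- names(ind)[vapply(ind, function(x)
    is.numeric(x) && sd(x) == 0, logical(1))]
  blocks <- purrr::map(blocks, setdiff, constant_ind)
  spec <- plspm_spec(
    blocks = blocks,
    paths = data.frame(
      from = c("plant", "plant", "abiotic", "plant", "abiotic", "biotic"),
      to = c("abiotic", "biotic", "biotic", "em_diversity", "em_diversity",
             "em_diversity")
    )
  )
  pls <- suppressWarnings(fit_plspm(ind, spec, seed = seed,
                                    boot = config$bootstrap_n))

  keystone <- suppressWarnings(keystone_diversity_correlations(
    roles, fungal,
    dplyr::inner_join(div, meta[c("sample", "plant_richness")], by = "sample")
  ))

  run <- structure(
    list(sim = sim, alpha = alpha, beta = beta, networks = nets,
         network_all = net_all, network_crosskingdom = net_ck,
         topology = topo, subnet = subnet, roles = roles,
         keystone = keystone, biotic = biotic, respratio = respratio,
         regressions = regressions, duncan = duncan, anova = anova_tbl,
         collinearity = screen, lmm = lmms, lmm_table = lmm_tbl,
         rf_abiotic = rf_abiotic, rf_biotic = rf_biotic,
         plspm = pls, indicators = ind,
         dropped_indicators = constant_ind, config = config),
    class = "emnet_run"
  )
  if (!is.null(out_dir)) write_run_artifacts(run, out_dir)
  invisible(run)
}

write_run_artifacts <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  tsv <- function(x, f) readr::write_tsv(tibble::as_tibble(x), p(f),
                                         progress = FALSE)
  js <- function(x, f) jsonlite::write_json(x, p(f), auto_unbox = TRUE,
                                            digits = 10, pretty = TRUE)
  write_abundance_table(run$sim$fungal_table, p("fungal_table.tsv"))
  write_abundance_table(run$sim$bacterial_table, p("bacterial_table.tsv"))
  write_study_metadata(run$sim$metadata, p("metadata.tsv"))
  truth <- run$sim$truth
  truth$params <- unclass(truth$params)
  js(truth, "truth.json")
  tsv(run$alpha, "alpha.tsv")
  for (nm in c("beta_sor", "beta_sim", "beta_sne")) {
    tsv(tibble::as_tibble(run$beta[[nm]], rownames = "sample"),
        paste0(nm, ".tsv"))
  }
  tsv(run$beta$summary, "beta_summary.tsv")
  for (ft in names(run$networks)) {
    write_network_graphml(run$networks[[ft]],
                          p(paste0("network_", ft, ".graphml")))
  }
  write_network_graphml(run$network_all, p("network_all.graphml"))
  write_network_graphml(run$network_crosskingdom,
                        p("network_crosskingdom.graphml"))
  tsv(run$topology, "topology.tsv")
  tsv(run$subnet, "subnet_metrics.tsv")
  tsv(run$roles, "roles.tsv")
  tsv(run$keystone, "keystone_correlations.tsv")
  tsv(run$biotic, "biotic_factors.tsv")
  tsv(run$respratio, "respratio.tsv")
  tsv(run$regressions, "regressions.tsv")
  tsv(run$anova, "anova.tsv")
  tsv(run$lmm_table, "lmm_table.tsv")
  tsv(dplyr::bind_rows(
    dplyr::mutate(run$rf_abiotic$importance, set = "abiotic"),
    dplyr::mutate(run$rf_biotic$importance, set = "biotic")
  ), "rf_importance.tsv")
  tsv(run$plspm$paths, "plspm_paths.tsv")
  tsv(run$plspm$effects, "plspm_effects.tsv")
  tsv(run$plspm$scores, "plspm_scores.tsv")
  js(list(gof = run$plspm$gof,
          r_squared = setNames(as.list(run$plspm$r_squared$r_squared),
                               run$plspm$r_squared$latent)),
     "plspm_gof.json")
  js(unclass(run$config), "run_config.json")
  invisible(out_dir)
}

#' @export
print.emnet_run <- function(x, ...) {
  cat("<emnet_run>\n")
  cat(sprintf("  samples: %d; fungal network (all): %d nodes / %d edges\n",
              nrow(x$sim$metadata), igraph::vcount(x$network_all$graph),
              igraph::ecount(x$network_all$graph)))
  cat(sprintf("  PLS-PM GoF: %.3f; keystones: %d\n",
              x$plspm$gof, sum(x$roles$role != "peripheral")))
  invisible(x)
}
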