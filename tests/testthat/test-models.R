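test_that("diversity regressions recover exact log-linear relations", {
  meta <- tibble::tibble(
    sample = paste0("s", 1:12),
    forest_type = rep(c("PF", "QPF", "QBF"), each = 4),
    plant_richness = rep(c(5, 10, 20, 40), 3)
  )
  div <- tibble::tibble(sample = meta$sample,
                        metric = meta$plant_richness^2) # slope 2 in log-log
  fits <- suppressWarnings(fit_diversity_regressions(div, meta)) # perfect fit
  overall <- fits[fits$group == "overall", ]
  expect_equal(overall$slope, 2)
  expect_equal(overall$r_squared, 1)
  expect_equal(overall$response_scale, "log")
  expect_setequal(fits$group, c("overall", "PF", "QPF", "QBF"))
  expect_equal(fits$slope, rep(2, 4))
})

test_that("regression transforms and degenerate groups behave", {
  meta <- tibble::tibble(sample = paste0("s", 1:6),
                         forest_type = rep(c("PF", "QPF"), each = 3),
                         plant_richness = c(2, 4, 8, 2, 4, 8))
  div <- tibble::tibble(sample = meta$sample,
                        spans_zero = c(-1, 0, 1, 2, -2, 1))
  fits <- suppressWarnings(fit_diversity_regressions(div, meta))
  expect_true(all(fits$response_scale == "raw"))
  fits_sl <- suppressWarnings(
    fit_diversity_regressions(div, meta, transform = "signed_log")
  )
  expect_true(all(fits_sl$response_scale == "signed_log"))
  expect_error(fit_diversity_regressions(div, meta, transform = "log"),
               "nonpositive")
  # R^2 equals squared Pearson correlation in simple regression
  set.seed(9)
  div2 <- tibble::tibble(sample = meta$sample, m = rlnorm(6))
  f2 <- fit_diversity_regressions(div2, meta)
  r <- cor(log(div2$m), log(meta$plant_richness))
  expect_equal(f2$r_squared[f2$group == "overall"], r^2)
})

test_that("ANOVA with Duncan letters matches hand decomposition", {
  d <- anova_duncan(c(1, 2, 3, 11, 12, 13, 21, 22, 23),
                    rep(c("g1", "g2", "g3"), each = 3))
  # SSB = 600 on 2 df, SSW = 6 on 6 df -> F = 300
  expect_equal(d$anova$f_statistic, 300)
  expect_equal(d$anova$df1, 2)
  expect_equal(d$anova$df2, 6)
  expect_equal(length(unique(d$groups$letters)), 3L)
  expect_equal(d$groups$group, c("g3", "g2", "g1")) # sorted by mean, desc

  same <- anova_duncan(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$anova$f_statistic, 0)
  expect_equal(unique(same$groups$letters), "a")
})

test_that("Duncan letter groups are contiguous over sorted means", {
  set.seed(14)
  for (i in 1:10) {
    vals <- rnorm(18, rep(c(0, 0.8, 2), each = 6))
    d <- anova_duncan(vals, rep(c("x", "y", "z"), each = 6))
    lets <- strsplit(d$groups$letters, "")
    for (l in unique(unlist(lets))) {
      has <- vapply(lets, function(x) l %in% x, logical(1))
      idx <- which(has)
      expect_equal(idx, seq(min(idx), max(idx))) # contiguous run
    }
  }
})

test_that("a zero-variance group is pooled, not fatal", {
  d <- anova_duncan(c(5, 5, 5, 1, 2, 3), rep(c("flat", "var"), each = 3))
  expect_true(is.finite(d$anova$f_statistic))
  expect_equal(nrow(d$groups), 2L)
})

test_that("collinearity screen matches exhaustive elimination", {
  # identical pair: exactly one survives
  two <- tibble::tibble(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4) * 2)
  expect_length(collinearity_filter(two, 0.6)$retained, 1L)

  # orthogonal variables all survive
  orth <- tibble::tibble(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1),
                         c = c(1, -1, -1, 1))
  expect_length(collinearity_filter(orth, 0.6)$retained, 3L)

  # 5-variable structure with two independent collinear pairs, where the
  # member to drop is unambiguous: compare greedy with every elimination order
  set.seed(20)
  n <- 200
  f1 <- rnorm(n)
  f2 <- rnorm(n)
  g <- rnorm(n)
  env <- tibble::tibble(
    v1 = f1 + 0.4 * g + rnorm(n, 0, 0.05), # collinear with v2, tied to v5
    v2 = f1 + rnorm(n, 0, 0.05),
    v3 = f2 + 0.4 * g + rnorm(n, 0, 0.05), # collinear with v4, tied to v5
    v4 = f2 + rnorm(n, 0, 0.05),
    v5 = g
  )
  got <- sort(collinearity_filter(env, 0.6)$retained)
  expect_equal(got, c("v2", "v4", "v5"))

  eliminate_all_orders <- function(r, cut) {
    viol <- which(r >= cut & upper.tri(r), arr.ind = TRUE)
    if (nrow(viol) == 0) return(list(sort(rownames(r))))
    out <- list()
    for (k in seq_len(nrow(viol))) {
      pair <- rownames(r)[viol[k, ]]
      drop_var <- pair[which.max(rowMeans(r[pair, , drop = FALSE]))]
      keep <- setdiff(rownames(r), drop_var)
      out <- c(out, eliminate_all_orders(r[keep, keep, drop = FALSE], cut))
    }
    unique(out)
  }
  r <- abs(cor(as.matrix(env)))
  diag(r) <- 0
  all_orders <- eliminate_all_orders(r, 0.6)
  expect_length(all_orders, 1L) # order-independent on this structure
  expect_equal(got, all_orders[[1]])
})

lmm_sim <- function(seed, n = 18, b_int = 0.3, site_sd = 0.3) {
  set.seed(seed)
  tibble::tibble(
    site = rep(paste0("st", 1:6), each = n / 6),
    plant_richness = rlnorm(n, 2.5, 0.5),
    SOC = rnorm(n)
  ) |>
    dplyr::mutate(
      y = 0.5 * as.numeric(scale(log(plant_richness))) + 0.4 * SOC +
        b_int * as.numeric(scale(log(plant_richness))) * SOC +
        rep(rnorm(6, 0, site_sd), each = n / 6) + rnorm(n, 0, 0.2)
    )
}

test_that("with no site variance the mixed model collapses to OLS", {
  found <- FALSE
  for (s in 1:10) {
    d <- lmm_sim(s, site_sd = 0)
    fit <- fit_interaction_lmm(d, "y", "SOC", site = "site",
                               standardize = FALSE)
    if (!fit$flags$singular) next
    found <- TRUE
    ols <- lm(y ~ plant_richness + SOC + plant_richness:SOC, data = d)
    expect_equal(fit$fixed$estimate, unname(coef(ols)), tolerance = 1e-6)
    expect_equal(fit$varcomp$variance[1], 0)
    break
  }
  expect_true(found)
})

test_that("the interaction coefficient is recovered across designs", {
  est <- vapply(1:20, function(s) {
    f <- suppressWarnings(fit_interaction_lmm(lmm_sim(s), "y", "SOC",
                                              site = "site"))
    f$fixed$estimate[f$fixed$term == "plant:env"]
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.3), 0.1)
})

test_that("constant covariates are rejected by name", {
  d <- lmm_sim(1)
  d$flatenv <- 5
  expect_error(fit_interaction_lmm(d, "y", "flatenv", site = "site"),
               "flatenv")
  expect_error(fit_interaction_lmm(d[1:3, ], "y", "SOC", site = "site"),
               "2 sites")
})

test_that("random forest ranks an exact predictor first", {
  top <- vapply(1:5, function(s) {
    set.seed(s)
    d <- tibble::tibble(x1 = rnorm(40), x2 = rnorm(40), x3 = rnorm(40))
    d$y <- d$x1
    rf <- rf_contributions(d, "y", c("x1", "x2", "x3"),
                           n_trees = 200, n_perm = 49, seed = s)
    rf$importance$predictor[which.max(rf$importance$inc_mse)]
  }, character(1))
  expect_true(all(top == "x1"))
})

test_that("duplicated predictors share importance", {
  set.seed(30)
  d <- tibble::tibble(x1 = rnorm(60), x2 = rnorm(60))
  d$y <- d$x1 + rnorm(60, 0, 0.3)
  solo <- rf_contributions(d, "y", c("x1", "x2"), n_trees = 300,
                           n_perm = 19, seed = 1)
  d$x1dup <- d$x1
  dup <- rf_contributions(d, "y", c("x1", "x1dup", "x2"), n_trees = 300,
                          n_perm = 19, seed = 1)
  imp <- function(r, v) r$importance$inc_mse[r$importance$predictor == v]
  expect_gt(imp(dup, "x1"), imp(dup, "x2"))
  expect_gt(imp(dup, "x1dup"), imp(dup, "x2"))
  expect_lt(imp(dup, "x1"), imp(solo, "x1"))
})

test_that("noise-only forests are flagged insignificant", {
  set.seed(31)
  d <- tibble::tibble(x1 = rnorm(30), x2 = rnorm(30), y = rnorm(30))
  rf <- rf_contributions(d, "y", c("x1", "x2"), n_trees = 200,
                         n_perm = 99, seed = 2)
  expect_lt(rf$r_squared, 0.3)
  expect_gt(rf$p_value, 0.05)
  expect_warning(
    rf_contributions(d[1:8, ], "y", c("x1", "x2"), n_trees = 50,
                     n_perm = 9, seed = 1),
    "fewer than 10"
  )
})
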