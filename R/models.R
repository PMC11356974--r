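#' Linear regressions of EM diversity metrics on plant richness
#'
#' For each EM diversity metric, fits ordinary least squares of the
#' (natural-log-transformed) metric on log plant richness — once over all
#' plots and once within each forest type — and reports slope, intercept,
#' \eqn{R^2}, and the two-sided slope p-value.
#'
#' Strictly positive metrics are log-transformed; metrics spanning zero or
#' negative values (such as the multi-complexity index) are kept on the
#' raw scale under `transform = "auto"` (the default), or mapped through a
#' signed shifted log \eqn{\mathrm{sign}(x)\log(1+|x|)} with
#' `transform = "signed_log"`. The scale actually used is recorded per
#' metric in the output.
#'
#' @param div Tibble with a `sample` column and numeric metric columns.
#' @param meta Study metadata with `sample`, `forest_type`,
#'   `plant_richness`.
#' @param metrics Metric columns to fit; defaults to all numeric columns
#'   of `div`.
#' @param transform `"auto"`, `"log"`, `"raw"`, or `"signed_log"`.
#' @param min_n Minimum plots per fitted group (groups below are skipped).
#' @return A tibble with class `"emnet_regressions"`: `metric`, `group`
#'   (`"overall"` or a forest type), `n`, `slope`, `intercept`,
#'   `r_squared`, `p_value`, `response_scale`.
#' @export
fit_diversity_regressions <- function(div, meta, metrics = NULL,
                                      transform = c("auto", "log", "raw", "signed_log"),
                                      min_n = 3L) {
  transform <- match.arg(transform)
  metrics <- metrics %||% names(div)[vapply(div, is.numeric, logical(1))]
  dat <- dplyr::inner_join(div, meta[c("sample", "forest_type", "plant_richness")],
                           by = "sample")
  if (any(dat$plant_richness <= 0)) abort("plant richness must be positive")
  lx <- log(dat$plant_richness)
  groups <- c("overall", sort(unique(dat$forest_type)))
  out <- purrr::map_dfr(metrics, function(mv) {
    y_raw <- dat[[mv]]
    scale_used <- switch(transform,
      log = "log",
      raw = "raw",
      signed_log = "signed_log",
      auto = if (all(y_raw > 0)) "log" else "raw"
    )
    y <- switch(scale_used,
      log = { if (any(y_raw <= 0)) abort(paste0("`", mv, "` has nonpositive values; cannot log")); log(y_raw) },
      raw = y_raw,
      signed_log = sign(y_raw) * log1p(abs(y_raw))
    )
    purrr::map_dfr(groups, function(gv) {
      sel <- if (gv == "overall") rep(TRUE, nrow(dat)) else dat$forest_type == gv
      if (sum(sel) < min_n) return(NULL)
      if (sd(lx[sel]) == 0) {
        warn(paste0("zero-variance plant richness in group ", gv, "; skipped"))
        return(NULL)
      }
      if (sd(y[sel]) == 0) {
        warn(paste0("`", mv, "` constant in group ", gv, "; skipped"))
        return(NULL)
      }
      fit <- lm(y[sel] ~ lx[sel])
      sm <- summary(fit)
      tibble::tibble(
        metric = mv, group = gv, n = sum(sel),
        slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
        r_squared = sm$r.squared,
        p_value = sm$coefficients[2, 4],
        response_scale = scale_used
      )
    })
  })
  structure(out, class = c("emnet_regressions", class(out)))
}

#' One-way ANOVA with Duncan's multiple range test
#'
#' Tests for a forest-type effect on a per-sample metric with one-way
#' ANOVA, then groups the type means with Duncan's multiple range test at
#' level `alpha`: the least significant range for a span of \eqn{p}
#' ordered means uses the studentized range at the Duncan protection
#' level \eqn{1 - (1-\alpha)^{p-1}}, with the harmonic mean group size
#' under unbalance. Means sharing a letter are not significantly
#' different.
#'
#' @param values Numeric per-sample metric.
#' @param groups Group labels, same length.
#' @param alpha Level of the range tests.
#' @return A list with class `"emnet_duncan"`: `anova` (one-row tibble
#'   with `f_statistic`, `df1`, `df2`, `p_value`) and `groups` (tibble
#'   with `group`, `n`, `mean`, `letters`, means sorted descending).
#' @examples
#' anova_duncan(c(1, 2, 3, 11, 12, 13, 21, 22, 23),
#'              rep(c("a", "b", "c"), each = 3))
#' @export
anova_duncan <- function(values, groups, alpha = 0.05) {
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups), nlevels(groups) >= 2L,
            all(table(groups) >= 2L))
  fit <- aov(values ~ groups)
  a <- anova(fit)
  mse <- a[["Mean Sq"]][2]
  df_err <- a[["Df"]][2]
  means <- sort(tapply(values, groups, mean), decreasing = TRUE)
  ns <- table(groups)[names(means)]
  n_h <- length(ns) / sum(1 / ns) # harmonic mean size
  g <- length(means)
  # pairwise decisions: span p ordered means -> Duncan critical range
  diff_mat <- matrix(FALSE, g, g, dimnames = list(names(means), names(means)))
  if (mse > 0) {
    for (i in seq_len(g - 1)) {
      for (j in (i + 1):g) {
        p_span <- j - i + 1
        q_crit <- qtukey((1 - alpha)^(p_span - 1), p_span, df_err)
        r_p <- q_crit * sqrt(mse / n_h)
        diff_mat[i, j] <- diff_mat[j, i] <- (means[i] - means[j]) > r_p
      }
    }
  }
  letters_vec <- insert_absorb_letters(diff_mat)
  out <- list(
    anova = tibble::tibble(
      f_statistic = a[["F value"]][1], df1 = a[["Df"]][1], df2 = df_err,
      p_value = a[["Pr(>F)"]][1]
    ),
    groups = tibble::tibble(
      group = names(means), n = as.integer(ns),
      mean = unname(means), letters = letters_vec
    )
  )
  structure(out, class = "emnet_duncan")
}

# letter display from a logical "significantly different" matrix over
# groups sorted by decreasing mean (insert-and-absorb)
insert_absorb_letters <- function(diff_mat) {
  g <- nrow(diff_mat)
  cols <- list(rep(TRUE, g)) # letter columns: membership masks
  for (i in seq_len(g - 1)) {
    for (j in (i + 1):g) {
      if (!diff_mat[i, j]) next
      for (k in seq_along(cols)) {
        if (cols[[k]][i] && cols[[k]][j]) {
          a <- cols[[k]]; a[i] <- FALSE
          b <- cols[[k]]; b[j] <- FALSE
          cols[[k]] <- a
          cols[[length(cols) + 1L]] <- b
        }
      }
      # absorb columns contained in another
      keep <- rep(TRUE, length(cols))
      for (k in seq_along(cols)) {
        for (l in seq_along(cols)) {
          if (k != l && keep[l] && all(cols[[k]] <= cols[[l]]) &&
              any(cols[[k]] < cols[[l]])) {
            keep[k] <- FALSE
            break
          }
        }
      }
      cols <- cols[keep]
    }
  }
  # order columns by first member so letters read top-down
  ord <- order(vapply(cols, function(x) which(x)[1], integer(1)))
  cols <- cols[ord]
  vapply(seq_len(g), function(i) {
    paste0(letters[which(vapply(cols, `[`, logical(1), i))], collapse = "")
  }, character(1))
}

#' Greedy collinearity screen for covariates
#'
#' Retains only weakly correlated covariates: while any pair has
#' \eqn{|r| \ge} `cut`, the worst pair is examined and the member with the
#' larger mean absolute correlation to all other covariates is dropped.
#'
#' @param env Tibble of numeric covariates (non-numeric columns are
#'   ignored).
#' @param cut Absolute-correlation threshold.
#' @return List with class `"emnet_collinearity"`: `retained` (character),
#'   `dropped` (tibble with `variable`, `partner`, `abs_r`,
#'   `mean_abs_r`).
#' @export
collinearity_filter <- function(env, cut = 0.6) {
  num <- env[vapply(env, is.numeric, logical(1))]
  if (ncol(num) < 2L) {
    return(structure(list(retained = names(num),
                          dropped = tibble::tibble(variable = character(),
                                                   partner = character(),
                                                   abs_r = double(),
                                                   mean_abs_r = double())),
                     class = "emnet_collinearity"))
  }
  r <- abs(cor(as.matrix(num)))
  diag(r) <- 0
  dropped <- list()
  while (max(r) >= cut && nrow(r) > 1L) {
    worst <- which(r == max(r), arr.ind = TRUE)[1, ]
    pair <- rownames(r)[worst]
    mean_r <- rowMeans(r[pair, , drop = FALSE])
    out_var <- pair[which.max(mean_r)]
    dropped[[length(dropped) + 1L]] <- tibble::tibble(
      variable = out_var, partner = setdiff(pair, out_var)[1],
      abs_r = max(r), mean_abs_r = max(mean_r)
    )
    keep <- setdiff(rownames(r), out_var)
    r <- r[keep, keep, drop = FALSE]
  }
  structure(
    list(retained = rownames(r) %||% names(num),
         dropped = dplyr::bind_rows(dropped)),
    class = "emnet_collinearity"
  )
}

#' Interaction linear mixed model of EM diversity on plant richness
#'
#' Fits, by REML, the random-intercept model
#' \deqn{y \sim \mathrm{plant} + \mathrm{env} + \mathrm{plant} \times
#'   \mathrm{env} + (1 | \mathrm{site}),}
#' so the environmental covariate moves both the intercept (main effect)
#' and the slope (interaction) of the plant-diversity relationship, with
#' sites as a random intercept. Fixed-effect p-values are Wald t-tests
#' with Satterthwaite degrees of freedom. Predictors are z-scored by
#' default so coefficients are comparable across covariates.
#'
#' @param data Tibble holding all model columns.
#' @param response Name of the response column (typically a
#'   log-transformed EM diversity metric).
#' @param env Name of the environmental covariate column.
#' @param plant Name of the plant-diversity column (log-transformed
#'   richness recommended).
#' @param site Name of the site (random-effect) column.
#' @param standardize z-score `plant` and `env` before fitting.
#' @return A list with class `"emnet_lmm"`: `fixed` (tibble of terms with
#'   estimate, SE, df, t, p), `varcomp` (site and residual variances),
#'   `fit` (the underlying `lmerMod`), `flags` (`singular`,
#'   `refit_ml`), and the variable names.
#' @export
fit_interaction_lmm <- function(data, response, env,
                                plant = "plant_richness", site = "site",
                                standardize = TRUE) {
  for (v in c(response, env, plant, site)) {
    if (is.null(data[[v]])) abort(paste0("no column `", v, "` in data"))
  }
  if (sd(data[[env]]) == 0) {
    abort(paste0("covariate `", env, "` is constant; interaction inestimable"))
  }
  if (length(unique(data[[site]])) < 2L) abort("need at least 2 sites")
  d <- tibble::tibble(
    y = data[[response]],
    plant = as.numeric(data[[plant]]),
    env = as.numeric(data[[env]]),
    site = factor(data[[site]])
  )
  if (standardize) {
    d$plant <- as.numeric(scale(d$plant))
    d$env <- as.numeric(scale(d$env))
  }
  flags <- list(singular = FALSE, refit_ml = FALSE)
  fit <- tryCatch(
    lmerTest::lmer(y ~ plant + env + plant:env + (1 | site), data = d,
                   REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular = "ignore")),
    error = identity
  )
  if (inherits(fit, "error") ||
      (!is.null(fit@optinfo$conv$lme4$messages) &&
       any(grepl("failed to converge", fit@optinfo$conv$lme4$messages)))) {
    flags$refit_ml <- TRUE
    fit <- lmerTest::lmer(y ~ plant + env + plant:env + (1 | site), data = d,
                          REML = FALSE,
                          control = lme4::lmerControl(check.conv.singular = "ignore"))
  }
  flags$singular <- lme4::isSingular(fit)
  cf <- coef(summary(fit))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_site <- vc$vcov[vc$grp == "site"]
  var_resid <- vc$vcov[vc$grp == "Residual"]
  structure(
    list(
      fixed = tibble::tibble(
        term = rownames(cf),
        estimate = unname(cf[, "Estimate"]), se = unname(cf[, "Std. Error"]),
        df = unname(cf[, "df"]), statistic = unname(cf[, "t value"]),
        p_value = unname(cf[, "Pr(>|t|)"])
      ),
      varcomp = tibble::tibble(
        component = c("site", "residual"),
        variance = c(var_site, var_resid)
      ),
      fit = fit, flags = flags,
      response = response, env = env, plant = plant, site = site,
      standardized = standardize
    ),
    class = "emnet_lmm"
  )
}

#' Random-forest contributions of environmental drivers
#'
#' Random-forest regression of an EM diversity metric on a set of
#' (pre-screened) abiotic or biotic predictors, reporting permutation
#' importance (% increase in MSE when a predictor is permuted), the
#' out-of-bag explained variance, and a model significance p-value
#' obtained by refitting the forest on `n_perm` permutations of the
#' response.
#'
#' @param data Tibble holding response and predictors.
#' @param response Response column name.
#' @param predictors Character vector of predictor columns.
#' @param n_trees Trees per forest.
#' @param n_perm Response permutations for the significance test.
#' @param seed Integer seed.
#' @return A list with class `"emnet_rf"`: `importance` (tibble
#'   `predictor`, `inc_mse`, `contribution_pct` — share of the positive
#'   importances), `r_squared` (OOB), `p_value`, `n`, `low_n` flag.
#' @export
rf_contributions <- function(data, response, predictors,
                             n_trees = 500L, n_perm = 999L, seed = 1L) {
  y <- data[[response]]
  x <- as.data.frame(data[predictors])
  stopifnot(!is.null(y), ncol(x) >= 1L, all(complete.cases(x)), !anyNA(y))
  low_n <- length(y) < 10L
  if (low_n) warn("fewer than 10 observations; random-forest results are fragile")
  mtry <- ceiling(length(predictors) / 3)
  set.seed(seed)
  rf <- randomForest::randomForest(x, y, ntree = n_trees, mtry = mtry,
                                   importance = TRUE)
  inc <- randomForest::importance(rf, type = 1, scale = TRUE)[, 1]
  inc[!is.finite(inc)] <- 0 # zero per-tree spread gives NaN z-scores
  pos <- pmax(inc, 0)
  contrib <- if (sum(pos) > 0) 100 * pos / sum(pos) else rep(NA_real_, length(pos))
  r2 <- rf$rsq[n_trees]
  perm_r2 <- vapply(seq_len(n_perm), function(i) {
    yp <- sample(y)
    rfp <- randomForest::randomForest(x, yp, ntree = n_trees, mtry = mtry)
    rfp$rsq[n_trees]
  }, numeric(1))
  p <- (1 + sum(perm_r2 >= r2)) / (n_perm + 1)
  structure(
    list(
      importance = tibble::tibble(
        predictor = names(inc), inc_mse = unname(inc),
        contribution_pct = unname(contrib)
      ),
      r_squared = r2, p_value = p, n = length(y), low_n = low_n,
      n_trees = n_trees, n_perm = n_perm
    ),
    class = "emnet_rf"
  )
}
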