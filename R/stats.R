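#' Grouped summary statistics
#'
#' Per-group n, mean, SD (n-1 denominator), min, max and coefficient of
#' variation CV = SD/mean — the shape of a trial summary table of BLUEs or
#' raw traits by phase and treatment.
#'
#' @param data a `data.frame`.
#' @param value name of the numeric column to summarize.
#' @param by character vector of grouping column names.
#' @return `data.frame` with one row per group. `cv` is `NA` (flagged in
#'   `cv_defined`) when the group mean is 0. Groups that are entirely
#'   missing are dropped and logged.
#' @export
summarize_traits <- function(data, value, by) {
  stopifnot(value %in% names(data), all(by %in% names(data)))
  x <- data[[value]]
  keep <- !is.na(x)
  if (!all(keep)) ryenue_log(sprintf("%d missing value(s) of %s dropped from summary",
                                     sum(!keep), value), "WARN")
  d <- data[keep, , drop = FALSE]
  if (!nrow(d)) stop("no non-missing values to summarize", call. = FALSE)
  g <- interaction(d[by], drop = TRUE, sep = ":")
  res <- do.call(rbind, lapply(split(seq_len(nrow(d)), g), function(i) {
    v <- d[[value]][i]
    m <- mean(v); s <- stats::sd(v)
    if (length(v) == 1L) s <- 0
    cbind(d[i[1], by, drop = FALSE],
          data.frame(n = length(v), mean = m, sd = s,
                     min = min(v), max = max(v),
                     cv = if (m == 0) NA_real_ else s / m,
                     cv_defined = m != 0))
  }))
  rownames(res) <- NULL
  res[do.call(order, res[by]), , drop = FALSE]
}

#' Pairwise Pearson correlation matrix with significance
#'
#' Pairwise-complete Pearson correlations between trait columns with
#' two-sided t-test p-values and the conventional significance stars
#' (* p<0.05, ** p<0.01, *** p<0.001) — the feature-biomass correlation
#' panel of an image-based screening trial.
#'
#' @param data a `data.frame`.
#' @param vars character vector of numeric column names.
#' @return object of class `trait_cor`: list with matrices `r`, `p`, `n`,
#'   `stars`. Cells with fewer than 3 complete pairs are `NA` and flagged.
#' @export
correlate_traits <- function(data, vars) {
  stopifnot(all(vars %in% names(data)))
  k <- length(vars)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  n <- matrix(0L, k, k, dimnames = list(vars, vars))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    x <- data[[vars[i]]]; y <- data[[vars[j]]]
    ok <- !is.na(x) & !is.na(y)
    n[i, j] <- sum(ok)
    if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
    if (n[i, j] < 3L) {
      ryenue_log(sprintf("correlation %s~%s: <3 complete pairs, flagged missing",
                         vars[i], vars[j]), "WARN")
      next
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson", alternative = "two.sided")
    r[i, j] <- unname(ct$estimate); p[i, j] <- ct$p.value
  }
  stars <- matrix("", k, k, dimnames = list(vars, vars))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  stars[!is.na(p) & p < 0.001] <- "***"
  diag(stars) <- ""
  structure(list(r = r, p = p, n = n, stars = stars), class = "trait_cor")
}

#' @export
print.trait_cor <- function(x, digits = 3, ...) {
  cat("Pairwise Pearson correlations (pairwise-complete):\n")
  print(round(x$r, digits))
  cat("\nSignificance (* p<0.05, ** p<0.01, *** p<0.001):\n")
  print(x$stars, quote = FALSE)
  invisible(x)
}

#' Mixed-model BLUEs for genotype-by-treatment cells
#'
#' Fits, per phase, the trial's linear mixed model by REML: genotype,
#' N treatment and their interaction as fixed effects, replicate as a
#' random intercept. Returns the best linear unbiased estimate (BLUE) and
#' standard error of every genotype x treatment cell, plus Wald chi-square
#' tests for the three fixed terms (numerator df G-1, T-1, (G-1)(T-1)).
#' On a balanced complete design the cell BLUEs equal the arithmetic cell
#' means — the exact oracle used by the test suite. With a single replicate
#' (no block variance estimable) the fit falls back to fixed-effects least
#' squares with a logged warning.
#'
#' @param data `data.frame` with columns `genotype`, `treatment`,
#'   `replicate` and the response.
#' @param response name of the numeric response column (e.g. `"DM"`,
#'   `"NUE"`).
#' @param per_treatment if `TRUE`, fit a separate genotype model within each
#'   treatment instead of the joint two-factor model.
#' @return object of class `blue_fit`: list with `blues` (genotype,
#'   treatment, estimate, se), `tests` (term, chisq, df, p), `model`.
#' @export
fit_blues <- function(data, response, per_treatment = FALSE) {
  stopifnot(all(c("genotype", "treatment", "replicate", response) %in% names(data)))
  d <- data[!is.na(data[[response]]), , drop = FALSE]
  d$genotype <- factor(d$genotype)
  d$treatment <- factor(d$treatment)
  d$replicate <- factor(d$replicate)
  d$.y <- d[[response]]

  if (per_treatment) {
    parts <- lapply(split(d, d$treatment), function(dd) {
      fit_blues_one(dd, interaction_model = FALSE)
    })
    blues <- do.call(rbind, lapply(names(parts), function(tr) {
      b <- parts[[tr]]$blues; b$treatment <- tr; b
    }))
    tests <- do.call(rbind, lapply(names(parts), function(tr) {
      t <- parts[[tr]]$tests; t$treatment <- tr; t
    }))
    return(structure(list(blues = blues, tests = tests,
                          model = lapply(parts, `[[`, "model")),
                     class = "blue_fit"))
  }
  structure(fit_blues_one(d, interaction_model = TRUE), class = "blue_fit")
}

fit_blues_one <- function(d, interaction_model = TRUE) {
  # sum-to-zero contrasts so Type-III Wald tests are meaningful
  stats::contrasts(d$genotype) <- stats::contr.sum(nlevels(d$genotype))
  if (interaction_model) {
    stats::contrasts(d$treatment) <- stats::contr.sum(nlevels(d$treatment))
  }
  fixed <- if (interaction_model) .y ~ genotype * treatment else .y ~ genotype
  n_rep <- nlevels(d$replicate)
  use_lmm <- n_rep >= 2L
  if (!use_lmm) {
    ryenue_log("single replicate: falling back to fixed-effects least squares", "WARN")
    fit <- stats::lm(fixed, data = d)
  } else {
    fit <- lme4::lmer(stats::as.formula(paste(deparse(fixed), "+ (1 | replicate)")),
                      data = d, REML = TRUE)
    if (lme4::isSingular(fit, tol = 1e-8)) {
      ryenue_log("block variance estimated at the boundary (singular fit); estimates remain valid",
                 "WARN")
    }
  }

  grid <- if (interaction_model) {
    expand.grid(genotype = levels(d$genotype), treatment = levels(d$treatment))
  } else {
    data.frame(genotype = levels(d$genotype))
  }
  grid$genotype <- factor(grid$genotype, levels = levels(d$genotype))
  stats::contrasts(grid$genotype) <- stats::contr.sum(nlevels(d$genotype))
  if (interaction_model) {
    grid$treatment <- factor(grid$treatment, levels = levels(d$treatment))
    stats::contrasts(grid$treatment) <- stats::contr.sum(nlevels(d$treatment))
  }
  X <- stats::model.matrix(stats::delete.response(stats::terms(fixed)), grid)
  beta <- if (use_lmm) lme4::fixef(fit) else stats::coef(fit)
  V <- as.matrix(stats::vcov(fit))
  est <- drop(X %*% beta)
  se <- sqrt(rowSums((X %*% V) * X))
  blues <- cbind(grid, data.frame(estimate = est, se = se))

  aov3 <- tryCatch(car::Anova(fit, type = 3, test.statistic = "Chisq"),
                   error = function(e) NULL)
  if (is.null(aov3)) {
    # e.g. saturated single-replicate fallback: no residual df for tests
    ryenue_log("fixed-effect tests unavailable (no residual degrees of freedom)", "WARN")
    tests <- data.frame(term = attr(stats::terms(fixed), "term.labels"),
                        statistic = NA_real_, df = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE)
  } else {
    terms_keep <- setdiff(rownames(aov3), c("(Intercept)", "Residuals"))
    stat_col <- intersect(c("Chisq", "F value"), colnames(aov3))[1]
    p_col <- grep("^Pr", colnames(aov3), value = TRUE)[1]
    tests <- data.frame(term = terms_keep,
                        statistic = aov3[terms_keep, stat_col],
                        df = aov3[terms_keep, "Df"],
                        p = aov3[terms_keep, p_col],
                        stringsAsFactors = FALSE)
    rownames(tests) <- NULL
  }
  list(blues = blues, tests = tests, model = fit)
}

#' @export
print.blue_fit <- function(x, ...) {
  cat("Genotype x treatment BLUEs (", nrow(x$blues), " cells)\n", sep = "")
  print(utils::head(x$blues, 6))
  cat("...\nFixed-effect Wald tests:\n")
  print(x$tests)
  invisible(x)
}

#' Recovery of true genotype effects from estimated BLUEs
#'
#' Validation harness for synthetic trials: correlates the generator's true
#' per-genotype growth multipliers with the estimated genotype BLUEs, per
#' treatment and averaged over treatments, and reports the overlap of the
#' top decile of genotypes (the selection a breeder would make).
#'
#' @param blue_fit result of [fit_blues()] on a synthetic trial response.
#' @param truth the [growth_truth()] object that generated the trial.
#' @return list: `per_treatment` data frame with Pearson and Spearman
#'   correlations per treatment, `overall` correlations of
#'   treatment-averaged BLUEs, and `top_decile_overlap` (fraction of the
#'   true top-decile genotypes recovered in the estimated top decile).
#' @export
recover_parameters <- function(blue_fit, truth) {
  b <- blue_fit$blues
  tmult <- truth$genotype_mult
  per_trt <- do.call(rbind, lapply(split(b, b$treatment), function(bb) {
    tv <- tmult[as.character(bb$genotype)]
    data.frame(treatment = bb$treatment[1],
               pearson = stats::cor(tv, bb$estimate, method = "pearson"),
               spearman = stats::cor(tv, bb$estimate, method = "spearman"))
  }))
  rownames(per_trt) <- NULL
  avg <- tapply(b$estimate, as.character(b$genotype), mean)
  tv <- tmult[names(avg)]
  overall <- data.frame(
    pearson = stats::cor(tv, avg, method = "pearson"),
    spearman = stats::cor(tv, avg, method = "spearman")
  )
  k <- max(1L, floor(length(tv) / 10))
  top_true <- names(sort(tv, decreasing = TRUE))[seq_len(k)]
  top_est <- names(sort(avg, decreasing = TRUE))[seq_len(k)]
  list(per_treatment = per_trt, overall = overall,
       top_decile_overlap = length(intersect(top_true, top_est)) / k)
}
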