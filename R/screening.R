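# Seeded synthetic voltage-dataset generator and the screening statistics:
# one-way ANOVA, residual diagnostics (Anderson-Darling normality, median-
# centered Levene), Fisher's protected LSD pairwise comparisons, and a
# compact-letter material ranking.

#' Specification for the synthetic voltage dataset
#'
#' Replicate voltages per material are drawn from Normal(mean, sigma^2) with
#' a common noise level, reproducibly per seed. The defaults emulate the
#' screening study conditions: the benchmark material means, sigma =
#' 0.0011 V and 30 replicates per material.
#'
#' @param means Named group means, V (default [reference_mean_voltages()]).
#' @param sigma Common noise standard deviation, V (positive).
#' @param n_per_group Replicates per material (at least 2).
#' @param seed Integer seed.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(means = reference_mean_voltages(),
                           sigma = 0.0011, n_per_group = 30, seed = 42) {
  if (is.null(names(means)) || anyDuplicated(names(means)))
    stop("'means' must be uniquely named by material", call. = FALSE)
  if (!is.finite(sigma) || sigma <= 0)
    stop("'sigma' must be positive", call. = FALSE)
  if (n_per_group < 2) stop("'n_per_group' must be >= 2", call. = FALSE)
  structure(list(means = means, sigma = sigma,
                 n_per_group = as.integer(n_per_group),
                 seed = as.integer(seed)),
            class = "generator_spec")
}

#' Generate a synthetic replicate-voltage dataset
#'
#' @param spec A [generator_spec()].
#' @return Long-format data frame of class `voltage_dataset` with columns
#'   `material` (factor) and `voltage_V`; the spec is kept as an attribute.
#'   The global RNG state is left untouched.
#' @export
generate_dataset <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "generator_spec"))
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(spec$seed)
  mats <- names(spec$means)
  v <- unlist(lapply(mats, function(m)
    stats::rnorm(spec$n_per_group, spec$means[[m]], spec$sigma)))
  if (any(v < 0)) {
    warning("negative voltages clipped at 0", call. = FALSE)
    v <- pmax(v, 0)
  }
  out <- data.frame(
    material = factor(rep(mats, each = spec$n_per_group), levels = mats),
    voltage_V = v)
  attr(out, "spec") <- spec
  class(out) <- c("voltage_dataset", "data.frame")
  out
}

check_dataset <- function(ds) {
  if (!is.data.frame(ds) || !all(c("material", "voltage_V") %in% names(ds)))
    stop("dataset needs columns 'material' and 'voltage_V'", call. = FALSE)
  n <- table(ds$material)
  if (length(n) < 2 || any(n < 2))
    stop("need >= 2 groups with >= 2 replicates each", call. = FALSE)
  invisible(ds)
}

#' One-way ANOVA of voltage on material
#'
#' Standard one-way decomposition fitted with [stats::aov()]; returns the
#' full table plus R^2 = SS_between / SS_total. With zero within-group
#' variance F is reported as `Inf` (p = 0) with a warning.
#'
#' @param ds A `voltage_dataset` (or any data frame with `material` and
#'   `voltage_V`).
#' @return An object of class `anova_result`.
#' @export
anova_oneway <- function(ds) {
  check_dataset(ds)
  ds$material <- factor(ds$material)
  fit <- stats::aov(voltage_V ~ material, data = ds)
  # aov warns on its own for an essentially perfect fit; the degenerate
  # case is detected and reported explicitly below
  tab <- suppressWarnings(stats::anova(fit))
  ssb <- tab[["Sum Sq"]][1]; ssw <- tab[["Sum Sq"]][2]
  dfb <- tab[["Df"]][1]; dfw <- tab[["Df"]][2]
  # degenerate within-group variation (identical replicates) shows up as
  # rounding noise in the aov sums; treat it as exactly zero
  if (ssw <= 0 || ssw <= 1e-12 * ssb) {
    warning("zero within-group variance; F reported as Inf", call. = FALSE)
    F <- Inf; p <- 0; msw <- 0
  } else {
    msw <- ssw / dfw
    F <- (ssb / dfb) / msw
    p <- stats::pf(F, dfb, dfw, lower.tail = FALSE)
  }
  structure(list(
    df_between = dfb, df_within = dfw,
    SS_between = ssb, SS_within = ssw, SS_total = ssb + ssw,
    MS_between = ssb / dfb, MS_within = msw,
    F = F, p = p, R2 = ssb / (ssb + ssw),
    group_means = tapply(ds$voltage_V, ds$material, mean),
    group_n = as.vector(table(ds$material)),
    groups = levels(ds$material)),
    class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("One-way ANOVA: voltage_V ~ material\n")
  cat(sprintf("  between: df = %d, SS = %.6g, MS = %.6g\n",
              x$df_between, x$SS_between, x$MS_between))
  cat(sprintf("  within:  df = %d, SS = %.6g, MS = %.6g\n",
              x$df_within, x$SS_within, x$MS_within))
  cat(sprintf("  F = %.4f, p = %.3g, R2 = %.4f\n", x$F, x$p, x$R2))
  invisible(x)
}

#' Residual diagnostics for the one-way model
#'
#' Residuals are value minus group mean. Normality is assessed with the
#' Anderson-Darling test on the pooled residuals; variance homogeneity with
#' the median-centered Levene (Brown-Forsythe) test.
#'
#' @param ds A `voltage_dataset`.
#' @return An object of class `diagnostics_result` with fields
#'   `ad_stat`, `ad_p`, `levene_stat`, `levene_p`.
#' @export
residual_diagnostics <- function(ds) {
  check_dataset(ds)
  ds$material <- factor(ds$material)
  res <- ds$voltage_V - stats::ave(ds$voltage_V, ds$material)
  ad <- nortest::ad.test(res)
  lev <- car::leveneTest(voltage_V ~ material, data = ds, center = stats::median)
  structure(list(ad_stat = unname(ad$statistic), ad_p = ad$p.value,
                 levene_stat = lev[1, "F value"],
                 levene_p = lev[1, "Pr(>F)"]),
            class = "diagnostics_result")
}

#' Fisher's (protected) LSD pairwise comparisons
#'
#' Unadjusted pairwise comparisons using the pooled within-group mean
#' square: for each pair (i, j),
#' `se = sqrt(MS_within (1/n_i + 1/n_j))` and the 100(1-alpha)% CI is
#' `diff +/- t(1-alpha/2, df_within) se`. To be interpreted only after a
#' significant omnibus F (protected LSD).
#'
#' @param ds A `voltage_dataset`.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `lsd_result`: data frame `pairs` with the
#'   difference, SE, critical t, CI bounds, p and significance flag, plus
#'   the omnibus [anova_oneway()] result.
#' @export
fisher_lsd <- function(ds, alpha = 0.05) {
  check_dataset(ds)
  an <- anova_oneway(ds)
  g <- an$groups
  mns <- an$group_means[g]
  ns <- stats::setNames(an$group_n, g)
  tcrit <- stats::qt(1 - alpha / 2, an$df_within)
  idx <- utils::combn(length(g), 2)
  pairs <- do.call(rbind, lapply(seq_len(ncol(idx)), function(k) {
    i <- idx[1, k]; j <- idx[2, k]
    d <- mns[[i]] - mns[[j]]
    se <- sqrt(an$MS_within * (1 / ns[[i]] + 1 / ns[[j]]))
    tstat <- if (se > 0) d / se else sign(d) * Inf
    data.frame(group1 = g[i], group2 = g[j], diff_V = d, se_V = se,
               t_crit = tcrit, ci_low_V = d - tcrit * se,
               ci_high_V = d + tcrit * se,
               p = 2 * stats::pt(abs(tstat), an$df_within, lower.tail = FALSE),
               significant = abs(tstat) > tcrit,
               stringsAsFactors = FALSE)
  }))
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, alpha = alpha, anova = an),
            class = "lsd_result")
}

#' Rank materials with a compact letter display
#'
#' Materials are sorted by group mean (descending; ties broken by name) and
#' assigned letters greedily so that materials sharing a letter are pairwise
#' non-significant under the LSD comparisons.
#'
#' @param anova An [anova_oneway()] result.
#' @param lsd A [fisher_lsd()] result from the same dataset.
#' @return Data frame with columns `material`, `mean_V`, `rank`, `letters`.
#' @export
rank_materials <- function(anova, lsd) {
  stopifnot(inherits(anova, "anova_result"), inherits(lsd, "lsd_result"))
  mns <- anova$group_means
  ord <- order(-mns, names(mns))
  g <- names(mns)[ord]
  sig <- function(a, b) {
    p <- lsd$pairs
    hit <- (p$group1 == a & p$group2 == b) | (p$group1 == b & p$group2 == a)
    any(p$significant[hit])
  }
  # greedy compact-letter assignment over groups in mean order
  sets <- list()
  for (m in g) {
    placed <- FALSE
    for (k in seq_along(sets)) {
      if (all(!vapply(sets[[k]], sig, logical(1), b = m))) {
        sets[[k]] <- c(sets[[k]], m)
        placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1L]] <- m
  }
  letter_of <- function(m)
    paste(letters[which(vapply(sets, function(s) m %in% s, logical(1)))],
          collapse = "")
  data.frame(material = g, mean_V = unname(mns[g]), rank = seq_along(g),
             letters = vapply(g, letter_of, character(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Run the full screening analysis
#'
#' Generates (or takes) a dataset and computes diagnostics, ANOVA, Fisher
#' LSD and the ranking in one call.
#'
#' @param spec A [generator_spec()]; ignored if `ds` is supplied.
#' @param ds Optional existing `voltage_dataset`.
#' @param alpha Significance level for the LSD comparisons.
#' @return List of class `screening_result` with elements `dataset`,
#'   `diagnostics`, `anova`, `lsd`, `ranking`.
#' @export
screen_materials <- function(spec = generator_spec(), ds = NULL,
                             alpha = 0.05) {
  if (is.null(ds)) ds <- generate_dataset(spec)
  an <- anova_oneway(ds)
  lsd <- fisher_lsd(ds, alpha)
  structure(list(dataset = ds,
                 diagnostics = residual_diagnostics(ds),
                 anova = an, lsd = lsd,
                 ranking = rank_materials(an, lsd)),
            class = "screening_result")
}
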