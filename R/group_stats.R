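# Normality-routed group comparisons: per-group Shapiro-Wilk at alpha = 0.05
# decides between one-way ANOVA (+ Tukey-Kramer or Holm-Sidak) and
# Kruskal-Wallis (+ Dunn); two-way designs use two-way ANOVA with Tukey post
# hoc on main effects and the interaction. Established base-R tests are
# called throughout; only Dunn's test and the Holm-Sidak step-down
# adjustment are implemented here (no installed package provides them).

shapiro_p_safe <- function(x) {
  # constant data has no normal-theory footing; treat as non-normal
  if (length(unique(x)) < 3) return(0)
  tryCatch(shapiro.test(x)$p.value, error = function(e) 0)
}

# Holm-Sidak step-down adjustment of raw p-values.
holm_sidak_adjust <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- cummax(pmin(adj, 1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Dunn's rank-based pairwise test after Kruskal-Wallis, with tie correction.
dunn_test <- function(values, groups, p_adjust = "bonferroni") {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  tie_tab <- table(r)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  mean_rank <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  levs <- levels(groups)
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  rows <- purrr::map(pairs, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n_g[[i]] + 1 / n_g[[j]]))
    z <- (mean_rank[[i]] - mean_rank[[j]]) / se
    tibble(comparison = paste(i, j, sep = " - "), estimate = unname(z),
           p_raw = 2 * pnorm(-abs(z)))
  })
  out <- list_rbind(rows)
  out$p_adj <- if (identical(p_adjust, "holm-sidak")) {
    holm_sidak_adjust(out$p_raw)
  } else {
    p.adjust(out$p_raw, method = p_adjust)
  }
  out
}

# Pairwise t-tests with pooled SD (the ANOVA error term), raw p-values.
pairwise_t_raw <- function(values, groups) {
  groups <- factor(groups)
  fit <- aov(values ~ groups)
  mse <- summary(fit)[[1]]["Residuals", "Mean Sq"]
  df_err <- summary(fit)[[1]]["Residuals", "Df"]
  means <- tapply(values, groups, mean)
  n_g <- tapply(values, groups, length)
  pairs <- utils::combn(levels(groups), 2, simplify = FALSE)
  rows <- purrr::map(pairs, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt(mse * (1 / n_g[[i]] + 1 / n_g[[j]]))
    tstat <- (means[[i]] - means[[j]]) / se
    tibble(comparison = paste(i, j, sep = " - "),
           estimate = unname(means[[i]] - means[[j]]),
           p_raw = 2 * stats::pt(-abs(tstat), df_err))
  })
  list_rbind(rows)
}

tukey_table <- function(fit, which = NULL) {
  tk <- if (is.null(which)) TukeyHSD(fit) else TukeyHSD(fit, which = which)
  rows <- purrr::imap(tk, function(tab, term) {
    tibble(term = term, comparison = sub("-", " - ", rownames(tab), fixed = TRUE),
           estimate = tab[, "diff"], p_adj = tab[, "p adj"])
  })
  list_rbind(rows)
}

#' Normality-routed group comparison
#'
#' One-way designs: each group is screened with a Shapiro-Wilk test at
#' `alpha`. If every group passes, the omnibus test is a one-way ANOVA
#' followed by Tukey-Kramer (default) or Holm-Sidak-adjusted pairwise t
#' tests; if any group fails, the omnibus is Kruskal-Wallis followed by
#' Dunn's test (Bonferroni-adjusted). Two-way designs fit
#' `value ~ condition * day` and report main effects plus the interaction
#' with Tukey post hoc tables. The chosen route and procedure names are
#' recorded in the result; adjusted p-values carry the four-level star
#' convention (*p<0.05 through ****p<0.0001).
#'
#' @param data A data frame. One-way: columns `value`, `group`. Two-way:
#'   columns `value`, `condition`, `day`.
#' @param design `"one-way"` or `"two-way"`.
#' @param posthoc `"auto"` (Tukey on the parametric route, Dunn otherwise),
#'   `"tukey"`, `"dunn"` or `"holm-sidak"` (parametric branch only).
#' @param alpha Significance level for the normality screen (default 0.05).
#' @return An object of class `comparison_result`: list with `route`,
#'   `omnibus` (tibble of term, statistic, df, p_value), `posthoc` (tibble
#'   of comparisons with adjusted p and stars), `shapiro` (per-group screen,
#'   one-way only), `procedure`, `alpha`.
#' @examples
#' set.seed(1)
#' d <- data.frame(value = c(rnorm(10), rnorm(10, 2)),
#'                 group = rep(c("a", "b"), each = 10))
#' route_and_compare(d)
#' @export
route_and_compare <- function(data, design = c("one-way", "two-way"),
                              posthoc = c("auto", "tukey", "dunn", "holm-sidak"),
                              alpha = 0.05) {
  design <- match.arg(design)
  posthoc <- match.arg(posthoc)
  if (alpha <= 0 || alpha >= 1) nq_abort("alpha must be in (0,1)", field = "alpha")
  data <- as_tibble(data)
  if (!"value" %in% names(data)) nq_abort("missing `value` column", field = "value")

  if (design == "two-way") {
    need <- c("condition", "day")
    if (!all(need %in% names(data))) {
      nq_abort("two-way design needs `condition` and `day` columns", field = "condition/day")
    }
    data$condition <- factor(data$condition)
    data$day <- factor(data$day)
    fit <- aov(value ~ condition * day, data = data)
    an <- summary(fit)[[1]]
    terms <- trimws(rownames(an))
    keep <- terms != "Residuals"
    omnibus <- tibble(term = terms[keep], statistic = an[keep, "F value"],
                      df = an[keep, "Df"], p_value = an[keep, "Pr(>F)"])
    ph <- tukey_table(fit)
    ph$stars <- p_stars(ph$p_adj)
    return(structure(list(route = "parametric", omnibus = omnibus,
                          posthoc = ph, shapiro = NULL,
                          procedure = "two-way ANOVA + Tukey",
                          alpha = alpha),
                     class = "comparison_result"))
  }

  if (!"group" %in% names(data)) nq_abort("missing `group` column", field = "group")
  data$group <- factor(data$group)
  n_g <- table(data$group)
  if (length(n_g) < 2) nq_abort("need at least 2 groups", field = "group")
  if (any(n_g < 3)) {
    nq_abort(sprintf("group(s) with n < 3: %s",
                     paste(names(n_g)[n_g < 3], collapse = ", ")), field = "group")
  }
  sw <- tibble(group = names(n_g),
               p_value = map_dbl(split(data$value, data$group), shapiro_p_safe))
  sw$normal <- sw$p_value > alpha
  parametric <- all(sw$normal)

  if (parametric) {
    fit <- aov(value ~ group, data = data)
    an <- summary(fit)[[1]]
    omnibus <- tibble(term = "group", statistic = an[1, "F value"],
                      df = an[1, "Df"], p_value = an[1, "Pr(>F)"])
    if (posthoc == "holm-sidak") {
      ph <- pairwise_t_raw(data$value, data$group)
      ph$p_adj <- holm_sidak_adjust(ph$p_raw)
      ph <- ph[, c("comparison", "estimate", "p_adj")]
      proc <- "one-way ANOVA + Holm-Sidak"
    } else {
      ph <- tukey_table(fit)[, c("comparison", "estimate", "p_adj")]
      proc <- "one-way ANOVA + Tukey-Kramer"
    }
    route <- "parametric"
  } else {
    kw <- suppressWarnings(kruskal.test(data$value, data$group))
    pval <- kw$p.value
    if (!is.finite(pval)) pval <- 1  # fully tied/degenerate data: no evidence
    omnibus <- tibble(term = "group", statistic = unname(kw$statistic),
                      df = unname(kw$parameter), p_value = pval)
    ph <- dunn_test(data$value, data$group)[, c("comparison", "estimate", "p_adj")]
    proc <- "Kruskal-Wallis + Dunn (Bonferroni)"
    route <- "nonparametric"
  }
  ph$stars <- p_stars(ph$p_adj)
  structure(list(route = route, omnibus = omnibus, posthoc = ph,
                 shapiro = sw, procedure = proc, alpha = alpha),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s (%s route)\n", x$procedure, x$route))
  cat("omnibus:\n"); print(x$omnibus)
  cat("post hoc:\n"); print(x$posthoc)
  invisible(x)
}

#' Post hoc comparison table of a routed comparison
#'
#' @param x A `comparison_result`.
#' @param ... Unused.
#' @return Tibble of pairwise comparisons with adjusted p-values and stars.
#' @export
tidy.comparison_result <- function(x, ...) x$posthoc

#' Omnibus summary of a routed comparison
#'
#' @param x A `comparison_result`.
#' @param ... Unused.
#' @return Tibble with the omnibus term(s), statistic, df, p-value, route
#'   and procedure.
#' @export
glance.comparison_result <- function(x, ...) {
  mutate(x$omnibus, route = x$route, procedure = x$procedure)
}

# Routed omnibus p-value only (fast path for simulation studies).
routed_omnibus_p <- function(values, groups, alpha = 0.05) {
  if (sd(values) == 0) return(1)
  normal <- all(map_dbl(split(values, groups), shapiro_p_safe) > alpha)
  p <- if (normal) {
    summary(aov(values ~ groups))[[1]][1, "Pr(>F)"]
  } else {
    suppressWarnings(kruskal.test(values, groups)$p.value)
  }
  if (!is.finite(p)) 1 else p
}

#' Empirical type-I error of the routed omnibus test
#'
#' Monte-Carlo validation harness for the routing rule: simulates `reps`
#' null datasets (all groups drawn from the same distribution), runs the
#' Shapiro-Wilk-routed omnibus test on each and reports the rejection rate
#' at `alpha`, which should sit within binomial error of `alpha`.
#'
#' @param n_groups Number of groups (default 3).
#' @param n Per-group sample size (default 10).
#' @param reps Number of simulated datasets (>= 500; default 2000).
#' @param rdist Sampling function taking a count, default [stats::rnorm].
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed.
#' @return Tibble with `rejection_rate`, `reps`, `alpha`, `route_parametric`
#'   (fraction of reps routed through ANOVA).
#' @export
type_i_error_check <- function(n_groups = 3, n = 10, reps = 2000,
                               rdist = stats::rnorm, alpha = 0.05, seed = 1L) {
  if (reps < 500) nq_abort("reps must be >= 500", field = "reps")
  set.seed(as.integer(seed))
  groups <- factor(rep(seq_len(n_groups), each = n))
  res <- vapply(seq_len(reps), function(i) {
    values <- rdist(n_groups * n)
    normal <- all(map_dbl(split(values, groups), shapiro_p_safe) > alpha)
    p <- if (normal) {
      summary(aov(values ~ groups))[[1]][1, "Pr(>F)"]
    } else {
      suppressWarnings(kruskal.test(values, groups)$p.value)
    }
    c(reject = is.finite(p) && p < alpha, parametric = normal)
  }, c(reject = FALSE, parametric = FALSE))
  tibble(rejection_rate = mean(res["reject", ]), reps = reps, alpha = alpha,
         route_parametric = mean(res["parametric", ]))
}
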