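# Group statistics: MANOVA -> per-metric ANOVA (Bonferroni) -> Tukey HSD
# for the texture metrics, and Kruskal-Wallis -> Dunn for non-parametric
# comparisons, with the star convention used throughout.

#' Assemble a tidy group table of per-replicate metric values
#'
#' @param condition,metric_name character vectors
#' @param value numeric vector (finite)
#' @param biological_replicate,technical_replicate replicate identifiers
#' @return data frame of class `group_table`
#' @export
group_table <- function(condition, value, metric_name = "metric",
                        biological_replicate = 1L,
                        technical_replicate = seq_along(value)) {
  df <- data.frame(condition = as.character(condition),
                   biological_replicate = biological_replicate,
                   technical_replicate = technical_replicate,
                   metric_name = metric_name,
                   value = value)
  if (!all(is.finite(df$value)))
    erq_stop("values must be finite", "invalid_table")
  key <- paste(df$condition, df$biological_replicate,
               df$technical_replicate, df$metric_name)
  if (anyDuplicated(key))
    erq_stop("duplicated (condition, replicate, metric) keys", "invalid_table")
  class(df) <- c("group_table", "data.frame")
  df
}

# long table -> wide matrix of metrics with a condition column
table_to_wide <- function(table, metrics) {
  stopifnot(all(metrics %in% table$metric_name))
  key <- paste(table$condition, table$biological_replicate,
               table$technical_replicate, sep = "\r")
  wide <- data.frame(key = unique(key))
  idx <- match(wide$key, key)
  wide$condition <- table$condition[idx]
  for (m in metrics) {
    sub <- table[table$metric_name == m, ]
    skey <- paste(sub$condition, sub$biological_replicate,
                  sub$technical_replicate, sep = "\r")
    wide[[m]] <- sub$value[match(wide$key, skey)]
  }
  if (anyNA(wide[metrics]))
    erq_stop("metrics are not complete for every replicate", "invalid_table")
  wide$key <- NULL
  wide
}

#' MANOVA, per-metric ANOVA with Bonferroni, and Tukey HSD on texture metrics
#'
#' The omnibus test is a one-way MANOVA on the joint metric vector,
#' reported with Pillai's trace and Roy's largest root. Each metric is then
#' tested by a one-way ANOVA with Bonferroni correction across the metric
#' family, and pairwise condition differences assessed by Tukey's honestly
#' significant difference test, with significance stars (`*` 0.05-0.01,
#' `**` 0.01-0.001, `***` <= 0.001).
#'
#' @param table a [group_table()] holding all metrics
#' @param metrics metric names forming the Bonferroni family
#' @return object of class `stats_report`: `manova` (data frame with
#'   Pillai and Roy statistics and p-values), `anova` (per-metric F, raw and
#'   Bonferroni-adjusted p), `posthoc` (Tukey pairwise table with stars)
#' @export
compare_texture <- function(table,
                            metrics = c("contrast", "correlation",
                                        "energy", "homogeneity")) {
  stopifnot(inherits(table, "data.frame"))
  wide <- table_to_wide(table, metrics)
  if (length(unique(wide$condition)) < 2)
    erq_stop("need >= 2 conditions", "invalid_table")
  if (min(base::table(wide$condition)) < 3)
    erq_stop("need >= 3 observations per condition", "invalid_table")

  Y <- as.matrix(wide[metrics])
  cond <- factor(wide$condition)
  if (length(metrics) == 1) {
    # one response: the multivariate tests coincide with the one-way ANOVA
    a <- summary(stats::aov(Y[, 1] ~ cond))[[1]]
    ssb <- a$`Sum Sq`[1]; ssw <- a$`Sum Sq`[2]
    man <- data.frame(test = c("Pillai", "Roy"),
                      statistic = c(ssb / (ssb + ssw), ssb / ssw),
                      approx_F = a$`F value`[1],
                      p_value = a$`Pr(>F)`[1])
  } else {
    man <- tryCatch({
      fit <- stats::manova(Y ~ cond)
      do.call(rbind, lapply(c("Pillai", "Roy"), function(tst) {
        s <- summary(fit, test = tst)$stats
        data.frame(test = tst, statistic = s[1, 2], approx_F = s[1, 3],
                   p_value = s[1, 6])
      }))
    }, error = function(e) {
      erq_stop(paste0("MANOVA failed (singular within-group covariance ",
                      "among ", paste(metrics, collapse = ", "), "): ",
                      conditionMessage(e)),
               "singular_covariance")
    })
  }

  an <- do.call(rbind, lapply(metrics, function(m) {
    a <- summary(stats::aov(wide[[m]] ~ cond))[[1]]
    data.frame(metric = m, F_value = a$`F value`[1], p_value = a$`Pr(>F)`[1])
  }))
  an$p_adjusted <- stats::p.adjust(an$p_value, method = "bonferroni")

  post <- do.call(rbind, lapply(metrics, function(m) {
    tk <- stats::TukeyHSD(stats::aov(wide[[m]] ~ cond))$cond
    data.frame(metric = m, comparison = rownames(tk),
               difference = tk[, "diff"], p_adjusted = tk[, "p adj"],
               stars = significance_stars(tk[, "p adj"]),
               row.names = NULL)
  }))

  structure(list(manova = man, anova = an, posthoc = post,
                 adjust_method = "bonferroni (across metrics) + Tukey HSD",
                 n_per_group = as.list(base::table(wide$condition))),
            class = "stats_report")
}

#' Kruskal-Wallis omnibus test with Dunn post-hoc comparisons
#'
#' The omnibus is [stats::kruskal.test()]. Dunn's test compares mean ranks
#' pairwise with the z statistic
#' \deqn{z = (\bar R_i - \bar R_j) / \sqrt{\left(\frac{N(N+1)}{12} -
#'   \frac{\sum (t^3 - t)}{12 (N-1)}\right)\left(\frac{1}{n_i} +
#'   \frac{1}{n_j}\right)}}
#' (tie-corrected), with two-sided p-values adjusted by `p_adjust_method`
#' (Holm by default) and starred.
#'
#' @param table a [group_table()]
#' @param metric metric name to compare (default: the only one present)
#' @param p_adjust_method adjustment for the Dunn pairwise family
#' @return object of class `stats_report`: `kruskal` (H statistic, df, p),
#'   `posthoc` (Dunn pairwise z, adjusted p, stars)
#' @export
compare_nonparam <- function(table, metric = NULL,
                             p_adjust_method = "holm") {
  stopifnot(inherits(table, "data.frame"))
  if (is.null(metric)) {
    metric <- unique(table$metric_name)
    stopifnot(length(metric) == 1)
  }
  sub <- table[table$metric_name == metric, ]
  g <- factor(sub$condition)
  if (nlevels(g) < 2) erq_stop("need >= 2 groups", "invalid_table")
  if (min(base::table(g)) < 2) erq_stop("need >= 2 observations per group",
                                  "invalid_table")
  kw <- stats::kruskal.test(sub$value, g)

  # Dunn pairwise comparisons on the joint ranks
  r <- rank(sub$value)
  N <- length(r)
  ties <- base::table(sub$value)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  var_term <- N * (N + 1) / 12 - tie_corr
  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    ri <- mean(r[g == i]); rj <- mean(r[g == j])
    ni <- sum(g == i); nj <- sum(g == j)
    se <- sqrt(var_term * (1 / ni + 1 / nj))
    z[k] <- if (se > 0) (ri - rj) / se else 0
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  padj <- stats::p.adjust(p, method = p_adjust_method)
  post <- data.frame(
    metric = metric,
    comparison = paste(pairs[1, ], pairs[2, ], sep = "-"),
    z = z, p_value = p, p_adjusted = padj,
    stars = significance_stars(padj))

  structure(list(
    kruskal = data.frame(metric = metric,
                         H = unname(kw$statistic),
                         df = unname(kw$parameter),
                         p_value = kw$p.value),
    posthoc = post,
    adjust_method = p_adjust_method,
    n_per_group = as.list(base::table(g))
  ), class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  if (!is.null(x$manova)) {
    cat("MANOVA omnibus:\n"); print(x$manova, row.names = FALSE)
    cat("Per-metric ANOVA (Bonferroni across metrics):\n")
    print(x$anova, row.names = FALSE)
  }
  if (!is.null(x$kruskal)) {
    cat("Kruskal-Wallis omnibus:\n"); print(x$kruskal, row.names = FALSE)
  }
  cat("Post-hoc comparisons:\n")
  print(x$posthoc, row.names = FALSE)
  invisible(x)
}
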