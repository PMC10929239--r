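# Group-comparison statistics used for stage outputs: two-tailed t-test,
# one- and two-way ANOVA, with Sidak or Tukey post-hoc adjustment, and
# mean +/- SEM summaries over the stated unit of analysis.

#' Sidak multiple-comparison adjustment
#'
#' `p_adj = 1 - (1 - p)^m`, capped at 1.
#'
#' @param p numeric vector of raw p values.
#' @param m number of comparisons in the family (default `length(p)`).
#' @return adjusted p values.
#' @export
sidak_adjust <- function(p, m = length(p)) {
  pmin(1, 1 - (1 - p)^m)
}

sem <- function(x) stats::sd(x) / sqrt(length(x))

group_summary <- function(df) {
  out <- do.call(rbind, lapply(split(df$value, df$group), function(v) {
    data.frame(n = length(v), mean = mean(v), sem = sem(v))
  }))
  data.frame(group = rownames(out), out, row.names = NULL)
}

#' Compare groups with the study's statistical designs
#'
#' Runs a two-tailed Student's t-test (pooled variance), a one-way ANOVA,
#' or a two-way ANOVA with interaction, with optional Sidak- or
#' Tukey-adjusted post-hoc contrasts, and reports group means +/- SEM.
#'
#' For `t_test_two_tailed` and `anova_1way`, pass `values` as a named list
#' of numeric vectors (one per group). For `anova_2way`, pass a data frame
#' with a `value` column and the two factor columns named in `factors`.
#' Degenerate inputs are handled, not thrown: with zero variance
#' everywhere and equal means the statistic is 0 and p = 1; with zero
#' within-group variance but different means the result is flagged
#' `degenerate` with an infinite statistic.
#'
#' @param values named list of numeric vectors, or a data frame (two-way).
#' @param design one of `"t_test_two_tailed"`, `"anova_1way"`,
#'   `"anova_2way"`.
#' @param factors for `anova_2way`: the two factor column names.
#' @param posthoc `"none"`, `"sidak"` or `"tukey"` (ANOVA designs only).
#' @param alpha significance level recorded in the result (default 0.05).
#' @return an object of class `ComparisonResult`: list with `design`,
#'   `statistic`, `df`, `p_value` (for two-way: `effects`, a per-term data
#'   frame), `posthoc` (data frame of contrasts with raw and adjusted p),
#'   `group_stats`, `degenerate`, `alpha`.
#' @export
compare_groups <- function(values,
                           design = c("t_test_two_tailed", "anova_1way", "anova_2way"),
                           factors = NULL,
                           posthoc = c("none", "sidak", "tukey"),
                           alpha = 0.05) {
  design <- match.arg(design)
  posthoc <- match.arg(posthoc)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (posthoc != "none" && design == "t_test_two_tailed") {
    stop("post-hoc adjustment applies to ANOVA designs only")
  }
  if (design == "anova_2way") {
    return(anova_two_way(values, factors, posthoc, alpha))
  }
  stopifnot(is.list(values), length(values) >= 2L, !is.null(names(values)))
  if (any(vapply(values, length, 1L) < 2L)) {
    stop("each group needs n >= 2 for variance-based tests")
  }
  df_long <- data.frame(value = unlist(values, use.names = FALSE),
                        group = factor(rep(names(values), vapply(values, length, 1L))))
  gs <- group_summary(df_long)
  if (design == "t_test_two_tailed") {
    if (length(values) != 2L) stop("the t-test compares exactly 2 groups")
    x <- values[[1]]; y <- values[[2]]
    n1 <- length(x); n2 <- length(y)
    sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
    if (sp2 == 0) {
      same <- mean(x) == mean(y)
      return(structure(list(design = design,
                            statistic = if (same) 0 else sign(mean(x) - mean(y)) * Inf,
                            df = n1 + n2 - 2L,
                            p_value = if (same) 1 else 0,
                            posthoc = NULL, group_stats = gs,
                            degenerate = !same, alpha = alpha),
                       class = "ComparisonResult"))
    }
    tt <- stats::t.test(x, y, var.equal = TRUE, alternative = "two.sided")
    return(structure(list(design = design,
                          statistic = unname(tt$statistic),
                          df = unname(tt$parameter),
                          p_value = tt$p.value,
                          posthoc = NULL, group_stats = gs,
                          degenerate = FALSE, alpha = alpha),
                     class = "ComparisonResult"))
  }
  # one-way ANOVA
  if (stats::var(df_long$value) == 0) {
    return(structure(list(design = design, statistic = 0,
                          df = c(length(values) - 1L, nrow(df_long) - length(values)),
                          p_value = 1, posthoc = NULL, group_stats = gs,
                          degenerate = FALSE, alpha = alpha),
                     class = "ComparisonResult"))
  }
  fit <- stats::aov(value ~ group, data = df_long)
  tab <- summary(fit)[[1]]
  res <- structure(list(design = design,
                        statistic = tab[["F value"]][1],
                        df = c(tab[["Df"]][1], tab[["Df"]][2]),
                        p_value = tab[["Pr(>F)"]][1],
                        posthoc = NULL, group_stats = gs,
                        degenerate = FALSE, alpha = alpha),
                   class = "ComparisonResult")
  if (posthoc != "none") res$posthoc <- posthoc_contrasts(fit, df_long, "group", posthoc)
  res
}

anova_two_way <- function(data, factors, posthoc, alpha) {
  stopifnot(is.data.frame(data), "value" %in% names(data),
            length(factors) == 2L, all(factors %in% names(data)))
  data[[factors[1]]] <- factor(data[[factors[1]]])
  data[[factors[2]]] <- factor(data[[factors[2]]])
  fml <- stats::as.formula(paste("value ~", factors[1], "*", factors[2]))
  fit <- stats::aov(fml, data = data)
  tab <- summary(fit)[[1]]
  terms <- trimws(rownames(tab))
  effects <- data.frame(term = terms[terms != "Residuals"],
                        df = tab[["Df"]][terms != "Residuals"],
                        statistic = tab[["F value"]][terms != "Residuals"],
                        p_value = tab[["Pr(>F)"]][terms != "Residuals"])
  df_long <- data.frame(value = data$value,
                        group = interaction(data[[factors[1]]], data[[factors[2]]],
                                            sep = ":"))
  res <- structure(list(design = "anova_2way",
                        statistic = effects$statistic,
                        df = c(effects$df, tab[["Df"]][terms == "Residuals"]),
                        p_value = effects$p_value,
                        effects = effects,
                        posthoc = NULL,
                        group_stats = group_summary(df_long),
                        degenerate = FALSE, alpha = alpha),
                   class = "ComparisonResult")
  if (posthoc != "none") {
    interaction_term <- paste0(factors[1], ":", factors[2])
    res$posthoc <- posthoc_contrasts(fit, df_long, interaction_term, posthoc)
  }
  res
}

# Pairwise contrasts with the selected family-wise adjustment. Tukey uses
# TukeyHSD on the fitted aov term; Sidak adjusts raw pairwise pooled-variance
# t-test p values by 1 - (1 - p)^m.
posthoc_contrasts <- function(fit, df_long, term, method) {
  if (method == "tukey") {
    th <- stats::TukeyHSD(fit, which = term)[[term]]
    return(data.frame(contrast = rownames(th),
                      diff = th[, "diff"],
                      p_raw = NA_real_,
                      p_adjusted = th[, "p adj"],
                      method = "tukey", row.names = NULL))
  }
  groups <- levels(df_long$group)
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    x <- df_long$value[df_long$group == pr[1]]
    y <- df_long$value[df_long$group == pr[2]]
    p <- if (length(x) > 1 && length(y) > 1 &&
             (stats::var(x) > 0 || stats::var(y) > 0)) {
      stats::t.test(x, y, var.equal = TRUE)$p.value
    } else if (mean(x) == mean(y)) 1 else 0
    data.frame(contrast = paste(pr[2], pr[1], sep = "-"),
               diff = mean(y) - mean(x), p_raw = p)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- sidak_adjust(out$p_raw, m = nrow(out))
  out$method <- "sidak"
  out
}

#' @export
print.ComparisonResult <- function(x, ...) {
  cat("ComparisonResult [", x$design, "]\n", sep = "")
  if (!is.null(x$effects)) {
    print(x$effects, row.names = FALSE)
  } else {
    cat("  statistic =", signif(x$statistic, 4),
        " df =", paste(x$df, collapse = ", "),
        " p =", signif(x$p_value, 4),
        if (x$degenerate) " (degenerate)", "\n")
  }
  if (!is.null(x$posthoc)) {
    cat("post-hoc (", x$posthoc$method[1], "):\n", sep = "")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}
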