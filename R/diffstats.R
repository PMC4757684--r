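# Differential pathway representation across sample groups (e.g. the three
# treatment plants): per pathway, availability scores are transformed
# (sqrt by default, the same scale used for display), compared with
# pairwise Welch t-tests plus a one-way ANOVA, and the ANOVA p-values are
# Benjamini-Hochberg adjusted across tested pathways.

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom (set `var_equal = TRUE` for the pooled-variance variant). When
#' both groups are constant the test is degenerate: equal means give
#' `t = 0, p = 1`, different means give an infinite-t / zero-p sentinel,
#' both flagged via `status`.
#'
#' @param x,y Numeric vectors with at least two values each.
#' @param var_equal Pool the variances instead of Welch's correction.
#' @return List: `t`, `p_two_sided`, `df`, `status` (`"ok"` or
#'   `"zero-variance"`).
#' @export
welch_t <- function(x, y, var_equal = FALSE) {
  if (length(x) < 2L || length(y) < 2L) {
    abort("each group needs at least two values")
  }
  if (var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, p_two_sided = 1, df = NA_real_,
                  status = "zero-variance"))
    }
    return(list(t = sign(mean(x) - mean(y)) * Inf, p_two_sided = 0,
                df = NA_real_, status = "zero-variance"))
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(tt$statistic), p_two_sided = tt$p.value,
       df = unname(tt$parameter), status = "ok")
}

#' Classical one-way ANOVA
#'
#' One-way F statistic on `k` groups with `N` observations, degrees of
#' freedom `(k - 1, N - k)`. Zero pooled within-group variance is
#' degenerate: identical group means give `F = 0, p = 1`, differing means an
#' infinite-F / zero-p sentinel, both flagged via `status`.
#'
#' @param groups List of numeric vectors, each with at least two values.
#' @return List: `F`, `p`, `df1`, `df2`, `status`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2L) abort("need at least two groups")
  if (any(lengths(groups) < 2L)) {
    abort("each group needs at least two values")
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  df1 <- length(groups) - 1L
  df2 <- length(values) - length(groups)
  if (ssw == 0) {
    gm <- vapply(groups, mean, numeric(1))
    if (max(gm) == min(gm)) {
      return(list(F = 0, p = 1, df1 = df1, df2 = df2,
                  status = "zero-variance"))
    }
    return(list(F = Inf, p = 0, df1 = df1, df2 = df2,
                status = "zero-variance"))
  }
  ow <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(F = unname(ow$statistic), p = ow$p.value,
       df1 = unname(ow$parameter[1]), df2 = unname(ow$parameter[2]),
       status = "ok")
}

#' Pathways differentially represented across sample groups
#'
#' @param avail An `avail_tbl` from [score_matrix()].
#' @param grouping Either a tibble with columns `sample_id`, `group`, or a
#'   named character vector `sample_id -> group`. Every referenced sample
#'   must exist in `avail`; at least two groups with two samples each.
#' @param transform Score transform applied before testing: `"sqrt"`
#'   (default, the display scale), `"none"`, or `"log1p"`.
#' @param var_equal Use pooled-variance t-tests instead of Welch.
#' @return A tibble of class `diff_tbl`, one row per pathway sorted by id:
#'   group mean columns (`mean_<group>`), `F`, `p_anova`, `q_anova`
#'   (Benjamini-Hochberg across tested pathways), a nested `pairwise`
#'   tibble of Welch results, and `status` (`tested`, `skipped-all-zero`,
#'   `skipped-zero-variance`). Raw p-values are reported alongside q-values.
#' @export
differential_pathways <- function(avail, grouping,
                                  transform = c("sqrt", "none", "log1p"),
                                  var_equal = FALSE) {
  transform <- match.arg(transform)
  if (!is.data.frame(grouping)) {
    grouping <- tibble(sample_id = names(grouping),
                       group = unname(grouping))
  }
  samples <- unique(avail$sample_id)
  unknown <- setdiff(grouping$sample_id, samples)
  if (length(unknown)) {
    abort(paste0("grouping references unknown sample(s): ",
                 paste(unknown, collapse = ", ")))
  }
  tab <- table(grouping$group)
  if (length(tab) < 2L || any(tab < 2L)) {
    abort("need >= 2 groups with >= 2 samples each")
  }
  tf <- switch(transform, sqrt = sqrt, none = identity, log1p = log1p)
  groups <- sort(unique(grouping$group))
  gmap <- setNames(grouping$group, grouping$sample_id)

  scored <- avail %>%
    filter(.data$sample_id %in% grouping$sample_id) %>%
    mutate(group = unname(gmap[.data$sample_id]),
           value = tf(.data$s_a))

  pids <- sort(unique(scored$pathway_id))
  rows <- purrr::map_dfr(pids, function(pid) {
    sub <- scored[scored$pathway_id == pid, ]
    vals <- split(sub$value, factor(sub$group, levels = groups))
    means <- vapply(vals, mean, numeric(1))
    base <- tibble(pathway_id = pid)
    for (g in groups) base[[paste0("mean_", g)]] <- means[[g]]
    if (all(sub$s_a == 0)) {
      return(base %>% mutate(F = NA_real_, p_anova = NA_real_,
                             status = "skipped-all-zero",
                             pairwise = list(NULL)))
    }
    if (var(sub$value) == 0) {
      return(base %>% mutate(F = NA_real_, p_anova = NA_real_,
                             status = "skipped-zero-variance",
                             pairwise = list(NULL)))
    }
    an <- one_way_anova(vals)
    pw <- purrr::map_dfr(utils::combn(groups, 2L, simplify = FALSE),
                         function(pr) {
      wt <- welch_t(vals[[pr[1]]], vals[[pr[2]]], var_equal = var_equal)
      tibble(group1 = pr[1], group2 = pr[2], t = wt$t, p = wt$p_two_sided)
    })
    base %>% mutate(F = an$F, p_anova = an$p, status = "tested",
                    pairwise = list(pw))
  })

  tested <- rows$status == "tested"
  rows$q_anova <- NA_real_
  rows$q_anova[tested] <- p.adjust(rows$p_anova[tested], method = "BH")
  rows <- rows %>%
    select("pathway_id", dplyr::starts_with("mean_"), "F", "p_anova",
           "q_anova", "status", "pairwise")
  structure(rows, class = c("diff_tbl", class(rows)),
            transform = transform, groups = groups)
}

#' Significance overview of a differential-pathway table
#'
#' @param object A `diff_tbl`.
#' @param alpha Significance threshold drawn as a dashed line.
#' @param ... Unused.
#' @return A ggplot object of -log10 adjusted p per pathway.
#' @export
autoplot.diff_tbl <- function(object, alpha = 0.05, ...) {
  df <- object %>% filter(.data$status == "tested")
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$pathway_id,
                                                      -.data$q_anova),
                                   y = -log10(.data$q_anova))) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(-log[10](q))) +
    ggplot2::theme_minimal()
}
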