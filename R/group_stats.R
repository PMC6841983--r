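#' Per-image metric records
#'
#' The statistics layer consumes a long-format data frame with one row per
#' (image, region): columns `image`, `group` (e.g. H / G / DR), `region`
#' (`whole`, `macula`, `optic_disc`), `db`, `lambda_mean`, `density_pct`.
#' [run_pipeline()] produces it; [metrics_record()] validates one built by
#' hand.
#'
#' @param df Data frame with the columns above.
#' @return The validated data frame (class `metrics_records`). Rows with
#'   `db` outside the interval 1..2 are flagged with a warning, not dropped: skeletons
#'   of degenerate masks can legitimately fall outside the curve-to-plane
#'   range.
#' @export
metrics_record <- function(df) {
  needed <- c("image", "group", "region", "db", "lambda_mean", "density_pct")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("metrics records missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df[, c("image", "region")])) {
    stop("duplicate (image, region) rows", call. = FALSE)
  }
  out_of_range <- which(df$db < 1 | df$db > 2)
  if (length(out_of_range)) {
    warning("db outside [1, 2] for row(s) ", paste(out_of_range, collapse = ", "),
            call. = FALSE)
  }
  class(df) <- unique(c("metrics_records", class(df)))
  df
}

new_comparison <- function(design, metric, table, statistic, p_value,
                           posthoc = NULL, letters = NULL, effects = NULL) {
  structure(list(design = design, metric = metric, table = table,
                 statistic = statistic, p_value = p_value,
                 posthoc = posthoc, letters = letters, effects = effects),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s on %s: statistic = %.4g, p = %.4g\n",
              x$design, x$metric, x$statistic, x$p_value))
  print(x$table, row.names = FALSE)
  if (!is.null(x$letters)) {
    cat("letters:", paste(names(x$letters), x$letters, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

summarise_levels <- function(values, levels) {
  agg <- tapply(values, levels, function(v) c(mean(v), stats::sd(v), length(v)))
  tab <- do.call(rbind, agg)
  data.frame(level = names(agg), mean = tab[, 1], sd = tab[, 2], n = tab[, 3],
             row.names = NULL)
}

#' Two-region t-test within one group
#'
#' Independent-samples two-tailed t-test between the two region levels of a
#' metric (e.g. macula vs optic disc in the healthy group). The classical
#' Student (pooled-variance) form is the default; Welch's correction is
#' available via `variant`.
#'
#' @param records A [metrics_record()] data frame restricted to one group
#'   and exactly two regions, each with n >= 2.
#' @param metric One of `"db"`, `"lambda_mean"`, `"density_pct"`.
#' @param variant `"student"` (equal variances, default) or `"welch"`.
#' @return A `comparison_result` with per-region mean, SD and n, the t
#'   statistic and the two-sided p-value.
#' @export
region_ttest <- function(records, metric = c("db", "lambda_mean", "density_pct"),
                         variant = c("student", "welch")) {
  metric <- match.arg(metric)
  variant <- match.arg(variant)
  lev <- unique(records$region)
  if (length(lev) != 2) {
    stop("region_ttest needs exactly two region levels, got ",
         length(lev), call. = FALSE)
  }
  y <- records[[metric]]
  g <- factor(records$region, levels = lev)
  if (any(table(g) < 2)) stop("each region needs n >= 2", call. = FALSE)
  tt <- stats::t.test(y ~ g, var.equal = (variant == "student"))
  new_comparison(design = "ttest", metric = metric,
                 table = summarise_levels(y, g),
                 statistic = unname(tt$statistic), p_value = tt$p.value)
}

#' One-way ANOVA with Tukey post-hoc over diagnostic groups
#'
#' Global (whole-retina) comparison of a metric across groups: one-way
#' ANOVA F-test, Tukey HSD adjusted pairwise p-values, and a compact letter
#' display at level `alpha` (groups sharing a letter are not significantly
#' different).
#'
#' @inheritParams region_ttest
#' @param records Records for one region, >= 2 groups with n >= 2 each.
#' @param alpha Significance level for the letters (default 0.05).
#' @return A `comparison_result`; `posthoc` holds the Tukey table and
#'   `letters` the per-group letter display.
#' @export
anova_oneway <- function(records, metric = c("db", "lambda_mean", "density_pct"),
                         alpha = 0.05) {
  metric <- match.arg(metric)
  y <- records[[metric]]
  g <- factor(records$group)
  if (nlevels(g) < 2 || any(table(g) < 2)) {
    stop("one-way ANOVA needs >= 2 groups with n >= 2 each", call. = FALSE)
  }
  res <- cell_anova(y, g, alpha)
  new_comparison(design = "anova1", metric = metric,
                 table = summarise_levels(y, g),
                 statistic = res$F, p_value = res$p,
                 posthoc = res$posthoc, letters = res$letters)
}

# one-way ANOVA + Tukey over the levels of `g`, with explicit handling of
# the degenerate zero-variance layouts (aov returns NaN F there): equal
# constants are "no effect" (F = 0, p = 1); distinct constants with zero
# within-group variance separate perfectly (F = Inf, p = 0)
cell_anova <- function(y, g, alpha) {
  means <- tapply(y, g, mean)
  lev <- names(means)
  pairs <- utils::combn(rev(lev), 2)
  pair_names <- paste(pairs[1, ], pairs[2, ], sep = "-")
  within0 <- all(tapply(y, g, stats::var) < 1e-25, na.rm = TRUE)
  if (within0) {
    same <- abs(means[pairs[1, ]] - means[pairs[2, ]]) < 1e-12
    p_adj <- ifelse(same, 1, 0)
    Fv <- if (all(same)) 0 else Inf
    posthoc <- data.frame(pair = pair_names,
                          diff = means[pairs[1, ]] - means[pairs[2, ]],
                          p_adj = p_adj, significant = p_adj < alpha,
                          row.names = NULL)
    letters <- compact_letters(posthoc$pair, posthoc$significant, means)
    return(list(F = Fv, p = if (all(same)) 1 else 0,
                posthoc = posthoc, letters = letters))
  }
  fit <- stats::aov(y ~ g)
  s <- summary(fit)[[1]]
  tuk <- stats::TukeyHSD(fit)$g
  posthoc <- data.frame(pair = rownames(tuk), diff = tuk[, "diff"],
                        p_adj = tuk[, "p adj"],
                        significant = tuk[, "p adj"] < alpha,
                        row.names = NULL)
  letters <- compact_letters(posthoc$pair, posthoc$significant, means)
  list(F = s[["F value"]][1], p = s[["Pr(>F)"]][1],
       posthoc = posthoc, letters = letters)
}

#' Two-way ANOVA (region x group) with Tukey over cell means
#'
#' Regional comparison: fits `metric ~ region * group` on a complete
#' 2-region x k-group layout, reports main-effect and interaction F tests,
#' and runs the Tukey HSD over the crossed cell means (the 6 region:group
#' cells in the standard design), with a compact letter display per cell.
#' On a balanced design the sums of squares are unambiguous (Type I/II/III
#' coincide).
#'
#' @inheritParams anova_oneway
#' @param records Records covering every region x group cell with n >= 2.
#' @return A `comparison_result`; `effects` is the full ANOVA table,
#'   `p_value` the interaction p, `posthoc`/`letters` refer to cell means.
#' @export
anova_twoway <- function(records, metric = c("db", "lambda_mean", "density_pct"),
                         alpha = 0.05) {
  metric <- match.arg(metric)
  y <- records[[metric]]
  region <- factor(records$region)
  group <- factor(records$group)
  cell_tab <- table(region, group)
  if (nlevels(region) < 2 || nlevels(group) < 2 || any(cell_tab < 2)) {
    stop("two-way ANOVA needs every region x group cell filled with n >= 2",
         call. = FALSE)
  }
  cell <- factor(paste(region, group, sep = ":"))
  if (stats::var(y) < 1e-25) {
    effects <- data.frame(term = c("region", "group", "region:group"),
                          df = c(nlevels(region) - 1L, nlevels(group) - 1L,
                                 (nlevels(region) - 1L) * (nlevels(group) - 1L)),
                          F = 0, p = 1)
  } else {
    fit <- stats::aov(y ~ region * group)
    s <- summary(fit)[[1]]
    effects <- data.frame(term = trimws(rownames(s)), df = s[["Df"]],
                          F = s[["F value"]], p = s[["Pr(>F)"]], row.names = NULL)
  }
  res <- cell_anova(y, cell, alpha)
  inter <- effects[effects$term == "region:group", ]
  new_comparison(design = "anova2", metric = metric,
                 table = summarise_levels(y, cell),
                 statistic = inter$F, p_value = inter$p,
                 posthoc = res$posthoc, letters = res$letters, effects = effects)
}

#' Compact letter display from a pairwise significance matrix
#'
#' Deterministic insert-and-absorb construction: starting from one set
#' containing all levels, every significant pair splits the sets containing
#' both members; redundant subsets are absorbed; letters are assigned `a`,
#' `b`, ... in order of descending level mean. Levels share a letter iff
#' they are not significantly different.
#'
#' @param pairs Character vector `"A-B"` naming each comparison.
#' @param significant Logical vector aligned with `pairs`.
#' @param means Named numeric vector of level means (drives letter order).
#' @return Named character vector of letter strings, one per level.
#' @export
compact_letters <- function(pairs, significant, means) {
  levels <- names(means)
  ord <- order(-means)
  levels <- levels[ord]
  sets <- list(levels)
  split_pair <- split_pairs(pairs, levels)
  for (i in which(significant)) {
    a <- split_pair[[i]][1]; b <- split_pair[[i]][2]
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb sets contained in another set
    keep <- rep(TRUE, length(new_sets))
    for (u in seq_along(new_sets)) {
      for (v in seq_along(new_sets)) {
        if (u != v && keep[u] && keep[v] &&
            all(new_sets[[u]] %in% new_sets[[v]]) &&
            (length(new_sets[[u]]) < length(new_sets[[v]]) || u > v)) {
          keep[u] <- FALSE
        }
      }
    }
    sets <- unique(new_sets[keep])
    sets <- sets[vapply(sets, length, 1L) > 0]
  }
  # order sets by the best (highest-mean) member for stable letter naming
  first_rank <- vapply(sets, function(s) min(match(s, levels)), 1)
  sets <- sets[order(first_rank)]
  out <- stats::setNames(rep("", length(levels)), levels)
  for (i in seq_along(sets)) {
    for (m in sets[[i]]) out[m] <- paste0(out[m], letters[i])
  }
  out[names(means)]
}

# parse "A-B" pair labels against known level names (levels may contain "-")
split_pairs <- function(pairs, levels) {
  lapply(pairs, function(p) {
    for (a in levels) {
      pref <- paste0(a, "-")
      if (startsWith(p, pref) && substring(p, nchar(pref) + 1) %in% levels) {
        return(c(a, substring(p, nchar(pref) + 1)))
      }
    }
    stop("cannot parse pair label: ", p, call. = FALSE)
  })
}
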