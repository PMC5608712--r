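# Cohort-level statistics: group summaries as mean +/- SEM, Student's t
# tests, one-way ANOVA with post hoc pairwise comparisons, and Pearson
# correlations between reconstructed modulus and remodeling measures.

#' Group summaries as mean +/- SEM
#'
#' @param data per-artery tibble.
#' @param metric column to summarize (tidy-eval).
#' @param group grouping column (tidy-eval, default `group`).
#' @return tibble with `n`, `mean`, `sem` (`SD/sqrt(n)`; 0 with
#'   `degenerate = TRUE` for n = 1) per group.
#' @export
summarize_groups <- function(data, metric, group = group) {
  metric <- rlang::enquo(metric); group <- rlang::enquo(group)
  out <- data |>
    dplyr::filter(!is.na(!!metric)) |>
    dplyr::group_by(!!group) |>
    dplyr::summarize(
      n = dplyr::n(),
      mean = mean(!!metric),
      sem = ifelse(dplyr::n() > 1, sd(!!metric) / sqrt(dplyr::n()), 0),
      degenerate = dplyr::n() < 2,
      .groups = "drop"
    )
  if (nrow(out) == 0 || any(out$n < 1)) stop("empty group", call. = FALSE)
  out
}

#' Two-group Student's t test
#'
#' Two-sided, equal-variance by default (the classical Student form); Welch
#' available via `var_equal = FALSE`.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @param var_equal pool variances (default TRUE).
#' @return one-row tibble: `statistic`, `df`, `p_value`, group means and
#'   SEMs, `method`.
#' @export
two_group_test <- function(a, b, var_equal = TRUE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  tt <- t.test(a, b, var.equal = var_equal)
  tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value,
         mean_a = mean(a), sem_a = sd(a) / sqrt(length(a)),
         mean_b = mean(b), sem_b = sd(b) / sqrt(length(b)),
         method = if (var_equal) "Student t (pooled)" else "Welch t")
}

#' One-way ANOVA across four experimental groups with post hoc t tests
#'
#' Post hoc pairwise Student's t tests are run only when the ANOVA p-value
#' falls below `p_threshold` (0.05 in the study protocol). No
#' multiple-testing correction is applied by default, mirroring the stated
#' procedure; `correction = "bonferroni"` is available and noted in the
#' output.
#'
#' @param data per-artery tibble.
#' @param metric metric column (tidy-eval).
#' @param group grouping column (tidy-eval); at least 4 distinct levels.
#' @param p_threshold gate for post hoc testing.
#' @param correction `"none"` (default) or `"bonferroni"`.
#' @return list: `anova` (one-row tibble: `f`, `df_between`, `df_within`,
#'   `p_value`) and `posthoc` (pairwise tibble, empty when not run).
#' @export
anova_posthoc <- function(data, metric, group = group, p_threshold = 0.05,
                          correction = c("none", "bonferroni")) {
  correction <- match.arg(correction)
  metric <- rlang::enquo(metric); group <- rlang::enquo(group)
  df <- tibble(y = dplyr::pull(data, !!metric),
               g = factor(dplyr::pull(data, !!group)))
  df <- df[!is.na(df$y), ]
  if (nlevels(droplevels(df$g)) < 4) {
    stop("one-way ANOVA here requires at least 4 groups", call. = FALSE)
  }
  df$g <- droplevels(df$g)
  if (any(table(df$g) < 2)) stop("each group needs >= 2 observations", call. = FALSE)
  fit <- aov(y ~ g, data = df)
  s <- summary(fit)[[1]]
  an <- tibble(f = s$`F value`[1], df_between = s$Df[1], df_within = s$Df[2],
               p_value = s$`Pr(>F)`[1])
  post <- tibble(group_a = character(), group_b = character(),
                 statistic = numeric(), df = numeric(), p_value = numeric())
  if (is.finite(an$p_value) && an$p_value < p_threshold) {
    lv <- levels(df$g)
    pairs <- utils::combn(lv, 2)
    post <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
      r <- two_group_test(df$y[df$g == pairs[1, k]], df$y[df$g == pairs[2, k]])
      tibble(group_a = pairs[1, k], group_b = pairs[2, k],
             statistic = r$statistic, df = r$df, p_value = r$p_value)
    })
    if (correction == "bonferroni") {
      message("applying Bonferroni correction over ", nrow(post), " contrasts")
      post$p_value <- pmin(1, post$p_value * nrow(post))
    }
  }
  list(anova = an, posthoc = post)
}

#' Pearson correlations of Young's modulus with remodeling measures
#'
#' Computes r and its exact t-transform p-value for modulus against each
#' requested variable, dropping pairs with missing values (the unmeasurable
#' sham intima is excluded, not zero-filled).
#'
#' @param data per-artery tibble containing `modulus` and the variables.
#' @param modulus modulus column (tidy-eval; default `modulus_kpa`).
#' @param vars character vector of column names to correlate against.
#' @return tibble: `variable`, `n`, `r`, `statistic`, `df`, `p_value`.
#' @export
modulus_correlations <- function(data, modulus = modulus_kpa,
                                 vars = c("intima_um3", "im_ratio",
                                          "strain_pct", "media_um3",
                                          "adventitia_um3")) {
  modulus <- rlang::enquo(modulus)
  x_all <- dplyr::pull(data, !!modulus)
  purrr::map_dfr(vars, function(v) {
    if (!v %in% names(data)) stop("no column '", v, "' in data", call. = FALSE)
    y_all <- data[[v]]
    ok <- !is.na(x_all) & !is.na(y_all)
    if (sum(ok) < 3) stop("fewer than 3 complete pairs for '", v, "'",
                          call. = FALSE)
    ct <- cor.test(x_all[ok], y_all[ok], method = "pearson")
    tibble(variable = v, n = sum(ok), r = unname(ct$estimate),
           statistic = unname(ct$statistic), df = unname(ct$parameter),
           p_value = ct$p.value)
  })
}
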