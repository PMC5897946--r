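#' Strain and family shares of phenotypic variance
#'
#' Random-intercept decomposition of a trait into strain,
#' family-within-strain and residual variance, fitted by REML with
#' `lme4::lmer(trait ~ 1 + (1 | strain) + (1 | strain:family))`.
#' Families are treated as nested within strain because families never
#' cross strains in the breeding design.  Single-member families should be
#' removed first (see [apply_exclusions()] purpose `"family_model"`).
#'
#' @param table Data frame with the trait, `strain` and `family` columns.
#' @param trait Trait column name.
#' @return Object of class `variance_shares`: named numeric
#'   `share_strain`, `share_family`, `share_residual` (fractions of total,
#'   summing to 1) with the underlying `lmerMod` in attribute `fit`.
#' @export
strain_family_shares <- function(table, trait = "spot_density") {
  need <- c(trait, "strain", "family")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  tab <- table[!is.na(table[[trait]]), , drop = FALSE]
  if (length(unique(tab$strain)) < 2) stop("need at least 2 strains")
  if (length(unique(tab$family)) < 2) stop("need at least 2 families")
  fml <- stats::as.formula(
    paste0("`", trait, "` ~ 1 + (1 | strain) + (1 | strain:family)"))
  fit <- lme4::lmer(fml, data = tab, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  v <- stats::setNames(vc$vcov, vc$grp)
  tot <- sum(v)
  out <- c(share_strain = unname(v["strain"] / tot),
           share_family = unname(v["strain:family"] / tot),
           share_residual = unname(v["Residual"] / tot))
  structure(out, fit = fit, class = c("variance_shares", "numeric"))
}

#' Fold difference between two group means
#'
#' @param mean_a,mean_b Group means; `mean_b` must be positive.
#' @return `mean_a / mean_b`.
#' @export
fold_difference <- function(mean_a, mean_b) {
  if (any(mean_b <= 0)) stop("denominator mean must be positive")
  mean_a / mean_b
}

#' Render a fold ratio the way results prose does
#'
#' One explicit convention covering the mixed styles seen in practice
#' ("1.4-fold", "6.5-fold", "sevenfold"): the ratio is rounded to
#' `digits` decimals; when the rounded value is a whole number it
#' collapses to the spelled form ("sevenfold") for 1-12, otherwise to
#' "7-fold"; non-integer roundings render as "6.5-fold".
#'
#' @param ratio Positive fold ratio.
#' @param digits Decimals to round to (default 1; use 0 to force the
#'   integer form).
#' @return Character rendering.
#' @examples
#' render_fold(1.02 / 0.14, digits = 0)  # "sevenfold"
#' render_fold(1.5 / 0.23)               # "6.5-fold"
#' @export
render_fold <- function(ratio, digits = 1) {
  if (ratio <= 0) stop("ratio must be positive")
  r <- round(ratio, digits)
  if (r == round(r)) {
    words <- c("one", "two", "three", "four", "five", "six", "seven",
               "eight", "nine", "ten", "eleven", "twelve")
    k <- as.integer(round(r))
    if (k >= 1 && k <= 12) paste0(words[k], "fold")
    else paste0(k, "-fold")
  } else paste0(format(r, nsmall = digits), "-fold")
}

#' Per-group summaries of a trait
#'
#' @param table Data frame.
#' @param by Grouping column name.
#' @param trait Trait column name.
#' @return Tibble `group`, `n`, `mean`, `median`, `sd` (sd is `NA` for
#'   single-observation groups; sample sd, `n - 1` denominator).
#' @export
group_summaries <- function(table, by, trait) {
  if (!by %in% names(table)) stop("grouping column not found: ", by)
  if (!trait %in% names(table)) stop("trait column not found: ", trait)
  tab <- table[!is.na(table[[trait]]), , drop = FALSE]
  groups <- split(tab[[trait]], tab[[by]])
  if (!length(groups)) stop("no groups to summarize")
  do.call(rbind, lapply(names(groups), function(g) {
    x <- groups[[g]]
    tibble::tibble(group = g, n = length(x), mean = mean(x),
                   median = stats::median(x),
                   sd = if (length(x) > 1) stats::sd(x) else NA_real_)
  }))
}

#' Two-group and k-group comparison tests
#'
#' Thin dispatch over the standard routines: Welch t test (fractional
#' degrees of freedom), Mann-Whitney (Wilcoxon rank-sum),
#' Kruskal-Wallis, or a one-way ANOVA reported as the proportion of
#' variance explained by the grouping factor (R^2).
#'
#' @param table Data frame.
#' @param response Response column name (numeric).
#' @param group Grouping column name.
#' @param kind One of `"t"`, `"mann_whitney"`, `"kruskal_wallis"`,
#'   `"anova_r2"`.
#' @return List with `statistic`, `df`, `p_value` and, for `"anova_r2"`,
#'   `r_squared`.
#' @export
group_tests <- function(table, response, group,
                        kind = c("t", "mann_whitney", "kruskal_wallis",
                                 "anova_r2")) {
  kind <- match.arg(kind)
  if (!response %in% names(table)) stop("response column not found")
  if (!group %in% names(table)) stop("group column not found")
  tab <- table[!is.na(table[[response]]) & !is.na(table[[group]]), ,
               drop = FALSE]
  g <- factor(tab[[group]])
  if (any(table(g) == 0) || nlevels(g) < 2) stop("need >= 2 non-empty groups")
  y <- tab[[response]]
  switch(kind,
    t = {
      if (nlevels(g) != 2) stop("t test needs exactly 2 groups")
      tt <- stats::t.test(y ~ g)  # Welch by default
      list(statistic = unname(tt$statistic), df = unname(tt$parameter),
           p_value = tt$p.value)
    },
    mann_whitney = {
      if (nlevels(g) != 2) stop("Mann-Whitney needs exactly 2 groups")
      # large-sample form without continuity correction, so that the
      # two-group Kruskal-Wallis test is its exact square
      wt <- stats::wilcox.test(y ~ g, exact = FALSE, correct = FALSE)
      list(statistic = unname(wt$statistic), df = NA_real_,
           p_value = wt$p.value)
    },
    kruskal_wallis = {
      kt <- stats::kruskal.test(y ~ g)
      list(statistic = unname(kt$statistic), df = unname(kt$parameter),
           p_value = kt$p.value)
    },
    anova_r2 = {
      fit <- stats::aov(y ~ g)
      sm <- summary(fit)[[1]]
      ss <- sm[["Sum Sq"]]
      list(statistic = sm[["F value"]][1],
           df = c(sm[["Df"]][1], sm[["Df"]][2]),
           p_value = sm[["Pr(>F)"]][1],
           r_squared = ss[1] / sum(ss))
    })
}
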