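# Comparative layer: functional-group summaries of shape descriptors and
# Pearson correlations between shape descriptors and safety factors, with
# Bonferroni control at m = 4 per safety-factor row (the convention of the
# source analysis; note 8 tests appear across the two rows).

#' Group mean and standard deviation of a shape descriptor
#'
#' @param table Data.frame with a `group` column and the named field.
#' @param field Column to summarize.
#' @return Data.frame with `group`, `n`, `mean`, `sd` (sample SD, n-1
#'   denominator; `NA` for singleton groups), ordered crush,
#'   probe_and_base, probe, tip.
#' @export
group_summary <- function(table, field) {
  if (!field %in% names(table)) stop("no column ", field)
  if (!"group" %in% names(table)) stop("table needs a group column")
  if (!all(table$group %in% beak_groups()))
    stop("unknown group label(s): ",
         paste(setdiff(table$group, beak_groups()), collapse = ", "))
  groups <- intersect(beak_groups(), unique(table$group))
  out <- do.call(rbind, lapply(groups, function(g) {
    x <- table[[field]][table$group == g]
    data.frame(group = g, n = length(x), mean = mean(x),
               sd = if (length(x) > 1) sd(x) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Pearson correlation with exact t-based p-value
#'
#' Product-moment correlation; the two-sided p-value uses the exact
#' transform `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of
#' freedom (no asymptotics: sample sizes here are at most 13).
#'
#' @param x,y Numeric vectors, length >= 3, non-constant.
#' @return List with `r`, `p`, `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) stop("constant input")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Bonferroni significance flags
#'
#' @param pvals Numeric p-values.
#' @param alpha Family-wise level.
#' @param m Number of tests in the family (default `length(pvals)`).
#' @return Logical vector: `p < alpha / m`.
#' @export
bonferroni_flags <- function(pvals, alpha = 0.05, m = length(pvals)) {
  if (m < 1) stop("m must be at least 1")
  pvals < alpha / m
}

.shape_fields <- c("ker_bottom_ratio", "ker_top_ratio", "depth_ratio",
                   "width_ratio")

#' Shape-descriptor versus safety-factor correlations
#'
#' Correlates the base- and tip-biting safety factors against the four shape
#' ratios (bottom keratin, top keratin, depth, width — each relative to beak
#' length), with Bonferroni control at m = 4 within each safety-factor row.
#'
#' @param table Data.frame with columns `SF_base`, `SF_tip` and the four
#'   shape-ratio columns (one row per model; >= 4 models).
#' @param alpha Family-wise level for the Bonferroni flags.
#' @return Data.frame with one row per (safety factor, shape ratio) pair:
#'   `sf`, `ratio`, `r`, `p`, `significant`.
#' @export
shape_safety_correlations <- function(table, alpha = 0.05) {
  need <- c(.shape_fields, "SF_base", "SF_tip")
  if (!all(need %in% names(table)))
    stop("table needs columns ", paste(need, collapse = ", "))
  if (nrow(table) < 4) stop("need at least 4 models")
  out <- do.call(rbind, lapply(c("SF_base", "SF_tip"), function(sf_col) {
    rows <- do.call(rbind, lapply(.shape_fields, function(f) {
      pr <- pearson(table[[f]], table[[sf_col]])
      data.frame(sf = sf_col, ratio = f, r = pr$r, p = pr$p)
    }))
    rows$significant <- bonferroni_flags(rows$p, alpha = alpha, m = 4)
    rows
  }))
  rownames(out) <- NULL
  out
}
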