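# Treatment statistics: one-way ANOVA + LSD post hoc, and the balanced
# two-factor ANOVA with interaction used for gradient x depth designs.
# Sums of squares come from stats::lm/anova; this file only shapes the
# output and enforces the design preconditions.

new_anova_result <- function(table, r_squared) {
  structure(list(table = table, r_squared = r_squared),
            class = "nema_anova")
}

#' One-way analysis of variance
#'
#' Standard between/within decomposition; `F = MSB / MSW` with p from the
#' F distribution. When the within-group mean square is zero, F is
#' infinite if groups differ and undefined (NA) if they do not.
#'
#' @param values Numeric response vector.
#' @param groups Group labels, same length as `values`.
#' @return A `nema_anova` object: `$table` with one row per source
#'   (`between`, `within`, `total`) and columns `df`, `ss`, `ms`, `F`, `p`;
#'   `$r_squared`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  keep <- !is.na(values)
  values <- values[keep]; groups <- droplevels(groups[keep])
  k <- nlevels(groups)
  if (k < 2) nf_stop("nema_design_error", "one-way ANOVA needs >= 2 groups")
  if (length(values) <= k) {
    nf_stop("nema_design_error",
            "one-way ANOVA needs more observations than groups")
  }
  fit <- stats::lm(values ~ groups)
  # anova.lm warns on near-perfect fits; the degenerate branches below give
  # those cases exact answers, so the warning is noise here
  a <- suppressWarnings(stats::anova(fit))
  ssb <- a$`Sum Sq`[1]; ssw <- a$`Sum Sq`[2]
  # zero out round-off-level sums of squares so constant data give exact
  # degenerate answers (F = 0, Inf or NA) instead of noise ratios
  tol <- 1e-12 * max(ssb + ssw, .Machine$double.eps)
  if (ssb <= tol) ssb <- 0
  if (ssw <= tol) ssw <- 0
  dfb <- a$Df[1]; dfw <- a$Df[2]
  msb <- ssb / dfb; msw <- ssw / dfw
  if (msw == 0) {
    f <- if (ssb == 0) NA_real_ else Inf
    p <- if (ssb == 0) NA_real_ else 0
  } else {
    f <- msb / msw
    p <- stats::pf(f, dfb, dfw, lower.tail = FALSE)
  }
  tab <- data.frame(
    source = c("between", "within", "total"),
    df = c(dfb, dfw, dfb + dfw),
    ss = c(ssb, ssw, ssb + ssw),
    ms = c(msb, msw, NA),
    F = c(f, NA, NA),
    p = c(p, NA, NA),
    stringsAsFactors = FALSE
  )
  new_anova_result(tab, r_squared = ssb / (ssb + ssw))
}

#' LSD pairwise comparisons
#'
#' Fisher's least significant difference using the pooled within-group
#' mean square: the pair (i, j) is significant iff
#' `|mean_i - mean_j| > t(1 - alpha/2, df_error) * sqrt(MSW (1/n_i + 1/n_j))`.
#'
#' @inheritParams one_way_anova
#' @param alpha Significance level, default 0.05.
#' @return Data frame with one row per group pair: `group1`, `group2`,
#'   `diff`, `lsd`, `p`, `significant`.
#' @export
lsd_pairwise <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  keep <- !is.na(values)
  values <- values[keep]; groups <- droplevels(groups[keep])
  aov_res <- one_way_anova(values, groups)
  dfw <- aov_res$table$df[2]
  msw <- aov_res$table$ms[2]
  if (dfw == 0) nf_stop("nema_design_error", "LSD needs error df > 0")
  mns <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  tcrit <- stats::qt(1 - alpha / 2, dfw)
  out <- do.call(rbind, apply(pairs, 2, function(pr) {
    d <- mns[[pr[1]]] - mns[[pr[2]]]
    se <- sqrt(msw * (1 / ns[[pr[1]]] + 1 / ns[[pr[2]]]))
    tval <- if (se == 0) ifelse(d == 0, 0, Inf * sign(d)) else d / se
    data.frame(group1 = pr[1], group2 = pr[2], diff = d,
               lsd = tcrit * se,
               p = 2 * stats::pt(abs(tval), dfw, lower.tail = FALSE),
               significant = abs(d) > tcrit * se,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Balanced two-factor ANOVA with interaction
#'
#' Main effects, interaction and error for a complete balanced
#' `a x b x r` design (`r >= 2` replicates per cell): degrees of freedom
#' `a-1`, `b-1`, `(a-1)(b-1)` and `ab(r-1)`, corrected total `abr - 1`.
#' Unbalanced or incomplete designs are rejected rather than silently
#' picking a sum-of-squares type.
#'
#' @param values Numeric response.
#' @param factor_a,factor_b Factor labels, same length as `values`.
#' @return A `nema_anova` object; `$table` rows are `factor_a`, `factor_b`,
#'   `interaction`, `error`, `total`; `$r_squared = 1 - SSE/SST`.
#' @export
two_way_anova_balanced <- function(values, factor_a, factor_b) {
  fa <- factor(factor_a); fb <- factor(factor_b)
  if (anyNA(values)) nf_stop("nema_design_error", "missing values not allowed")
  cell_n <- table(fa, fb)
  if (length(unique(as.vector(cell_n))) != 1 || any(cell_n < 2)) {
    nf_stop("nema_design_error",
            "design must be complete and balanced with >= 2 replicates per cell; use the one-way path otherwise")
  }
  fit <- stats::lm(values ~ fa * fb)
  a <- stats::anova(fit)
  ss <- a$`Sum Sq`; df <- a$Df
  sst <- sum(ss)
  ms <- ss / df
  f <- c(ms[1:3] / ms[4], NA)
  p <- c(stats::pf(f[1:3], df[1:3], df[4], lower.tail = FALSE), NA)
  tab <- data.frame(
    source = c("factor_a", "factor_b", "interaction", "error", "total"),
    df = c(df, sum(df)),
    ss = c(ss, sst),
    ms = c(ms, NA),
    F = c(f, NA),
    p = c(p, NA),
    stringsAsFactors = FALSE
  )
  new_anova_result(tab, r_squared = 1 - ss[4] / sst)
}

#' @export
print.nema_anova <- function(x, ...) {
  cat("Analysis of variance\n")
  tab <- x$table
  tab$ss <- signif(tab$ss, 6); tab$ms <- signif(tab$ms, 6)
  tab$F <- signif(tab$F, 4); tab$p <- signif(tab$p, 4)
  print(tab, row.names = FALSE)
  cat(sprintf("R-squared: %.3f\n", x$r_squared))
  invisible(x)
}

#' Write an ANOVA table to CSV
#'
#' Columns `source,df,mean_square,F,p`.
#'
#' @param x A `nema_anova`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_anova_csv <- function(x, path) {
  out <- data.frame(source = x$table$source, df = x$table$df,
                    mean_square = x$table$ms, F = x$table$F, p = x$table$p)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
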