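#' Build a tidy density table
#'
#' One row per subject x region x proximity class, carrying a non-negative
#' density value (mean crossings per probe, or L_V). This is the exchange
#' format between the simulation pipeline and the group statistics.
#'
#' @param subject,genotype,age,region,class,value Vectors of equal length;
#'   `class` defaults to `"overall"`. Ages are in months.
#' @return A `density_table` data frame.
#' @export
density_table <- function(subject, genotype, age, region,
                          value, class = "overall") {
  out <- data.frame(subject = as.character(subject),
                    genotype = as.character(genotype),
                    age = as.numeric(age),
                    region = as.character(region),
                    class = as.character(class),
                    value = as.numeric(value))
  if (any(!is.finite(out$value)) || any(out$value < 0))
    stop("density values must be finite and >= 0", call. = FALSE)
  key <- with(out, paste(subject, region, class, sep = "\r"))
  if (anyDuplicated(key))
    stop("one row per subject x region x class expected", call. = FALSE)
  class(out) <- c("density_table", class(out))
  out
}

#' Per-group mean and standard error
#'
#' `SEM = SD / sqrt(n)`; a single-observation group is flagged with
#' `sem = NA`.
#'
#' @param table A `density_table` (or any data frame with `value`).
#' @param by Grouping columns (default genotype, age, region, class).
#' @return Data frame of group `n`, `mean`, `sd`, `sem`.
#' @export
summarize_groups <- function(table,
                             by = c("genotype", "age", "region", "class")) {
  by <- intersect(by, names(table))
  f <- interaction(table[by], drop = TRUE, lex.order = TRUE)
  split_vals <- split(table$value, f)
  keys <- do.call(rbind, strsplit(names(split_vals), ".", fixed = TRUE))
  out <- as.data.frame(keys)
  names(out) <- by
  out$n <- vapply(split_vals, length, 0L)
  out$mean <- vapply(split_vals, mean, 0)
  out$sd <- vapply(split_vals, function(v) if (length(v) > 1) sd(v) else NA_real_, 0)
  out$sem <- out$sd / sqrt(out$n)
  rownames(out) <- NULL
  out
}

#' Normalize densities to the non-transgenic reference group
#'
#' Each value is rescaled to percent of the genotype-reference group mean
#' in the matching stratum (region x age x class by default, or pooled
#' across ages). Reference rows average 100 afterwards, so normalizing an
#' already-normalized table is a no-op.
#'
#' @param table A `density_table`.
#' @param reference_genotype Reference group label (default `"nTg"`).
#' @param pool_ages If `TRUE` the reference mean pools all ages within a
#'   region instead of age-matching (default `FALSE`).
#' @return The table with `value` in percent of the reference mean.
#' @export
normalize_to_ntg <- function(table, reference_genotype = "nTg",
                             pool_ages = FALSE) {
  by <- if (pool_ages) "region" else c("region", "age")
  by <- intersect(by, names(table))
  key <- do.call(paste, c(table[by], sep = "\r"))
  ref <- table$genotype == reference_genotype
  if (!any(ref))
    stop(sprintf("no rows for reference genotype '%s'", reference_genotype),
         call. = FALSE)
  # the reference is the control group's overall density in the matching
  # region (and age): proximity strata are expressed against it
  if ("class" %in% names(table) && any(table$class[ref] == "overall"))
    ref <- ref & table$class == "overall"
  ref_means <- tapply(table$value[ref], key[ref], mean)
  missing <- setdiff(unique(key), names(ref_means))
  if (length(missing))
    stop(sprintf("missing %s stratum for: %s", reference_genotype,
                 paste(gsub("\r", "/", missing), collapse = ", ")),
         call. = FALSE)
  table$value <- 100 * table$value / as.numeric(ref_means[key])
  table
}

# guarded F p-value: zero effect SS -> F = 0, p = 1 even when the residual
# variance is also zero (all-equal data)
f_stat <- function(ss_eff, df_eff, ms_res, df_res, tol = 1e-12) {
  if (ss_eff <= tol * max(ss_eff, 1)) return(c(F = 0, p = 1))
  if (ms_res <= 0) return(c(F = Inf, p = 0))
  f <- (ss_eff / df_eff) / ms_res
  c(F = f, p = pf(f, df_eff, df_res, lower.tail = FALSE))
}

#' One- or two-way fixed-effects ANOVA on a density table
#'
#' One factor gives the classical one-way decomposition; two factors give a
#' two-way ANOVA with interaction, with type-II sums of squares
#' (each main effect adjusted for the other, the interaction adjusted for
#' both), which reduces to the standard balanced-design formulas when the
#' design is balanced.
#'
#' @param table A `density_table` or data frame with a `value` column.
#' @param factors One or two column names to use as factors.
#' @param response Response column (default `"value"`).
#' @return Data frame with one row per effect: `term`, `df`, `sumsq`,
#'   `F`, `p`, plus a residual row.
#' @export
#' @examples
#' d <- data.frame(g = rep(c("a", "b"), each = 3), value = c(1, 2, 3, 2, 3, 4))
#' anova_table(d, "g")
anova_table <- function(table, factors, response = "value") {
  stopifnot(length(factors) %in% 1:2, all(factors %in% names(table)))
  dat <- data.frame(y = table[[response]],
                    lapply(table[factors], factor))
  names(dat) <- c("y", factors)
  for (f in factors) {
    if (nlevels(dat[[f]]) < 2)
      stop(sprintf("factor '%s' needs >= 2 levels", f), call. = FALSE)
  }
  if (length(factors) == 1L) {
    a <- factors[1]
    fit <- lm(stats::reformulate(a, "y"), dat)
    rss0 <- sum(resid(lm(y ~ 1, dat))^2)
    rss1 <- sum(resid(fit)^2)
    df_res <- df.residual(fit)
    ms_res <- rss1 / df_res
    fp <- f_stat(rss0 - rss1, nlevels(dat[[a]]) - 1, ms_res, df_res)
    return(data.frame(
      term = c(a, "Residuals"),
      df = c(nlevels(dat[[a]]) - 1, df_res),
      sumsq = c(rss0 - rss1, rss1),
      F = c(fp[["F"]], NA), p = c(fp[["p"]], NA)))
  }
  a <- factors[1]; b <- factors[2]
  tab <- table(dat[[a]], dat[[b]])
  if (any(tab < 1))
    stop("empty factor cells; every A x B combination needs data", call. = FALSE)
  if (any(tab < 2))
    stop("need >= 2 replicates per cell for the interaction model", call. = FALSE)
  rss <- function(fml) sum(resid(lm(fml, dat))^2)
  full <- lm(stats::as.formula(sprintf("y ~ %s * %s", a, b)), dat)
  rss_full <- sum(resid(full)^2)
  df_res <- df.residual(full)
  ms_res <- rss_full / df_res
  ss_a <- rss(stats::as.formula(sprintf("y ~ %s", b))) -
    rss(stats::as.formula(sprintf("y ~ %s + %s", a, b)))
  ss_b <- rss(stats::as.formula(sprintf("y ~ %s", a))) -
    rss(stats::as.formula(sprintf("y ~ %s + %s", a, b)))
  ss_ab <- rss(stats::as.formula(sprintf("y ~ %s + %s", a, b))) - rss_full
  df_a <- nlevels(dat[[a]]) - 1
  df_b <- nlevels(dat[[b]]) - 1
  df_ab <- df_a * df_b
  fa <- f_stat(ss_a, df_a, ms_res, df_res)
  fb <- f_stat(ss_b, df_b, ms_res, df_res)
  fab <- f_stat(ss_ab, df_ab, ms_res, df_res)
  data.frame(
    term = c(a, b, paste0(a, ":", b), "Residuals"),
    df = c(df_a, df_b, df_ab, df_res),
    sumsq = c(ss_a, ss_b, ss_ab, rss_full),
    F = c(fa[["F"]], fb[["F"]], fab[["F"]], NA),
    p = c(fa[["p"]], fb[["p"]], fab[["p"]], NA))
}

#' Post-hoc pairwise comparisons after ANOVA
#'
#' Pairwise group comparisons using the pooled within-group mean square:
#' Tukey's HSD (studentized range over the full set of means,
#' Tukey-Kramer for unequal n), Newman-Keuls (studentized range with the
#' span of each pair in the ordered means, constrained so a pair is never
#' more significant than a range that contains it), or Fisher's LSD
#' (unadjusted t). For every pair, `p(tukey) >= p(newman_keuls) >=
#' p(fisher_lsd)`.
#'
#' @param table A `density_table` or data frame with `value`.
#' @param factor_name Grouping column.
#' @param method `"tukey"` (default), `"newman_keuls"` or `"fisher_lsd"`.
#' @param response Response column.
#' @return Data frame of pairs: `group1`, `group2`, `diff`, `p`, `tier`
#'   (significance tier letters), with the method in the `"method"`
#'   attribute.
#' @export
posthoc_pairwise <- function(table, factor_name,
                             method = c("tukey", "newman_keuls", "fisher_lsd"),
                             response = "value") {
  method <- match.arg(method)
  g <- factor(table[[factor_name]])
  y <- table[[response]]
  k <- nlevels(g)
  if (k < 2) stop("need >= 2 groups", call. = FALSE)
  ns <- tapply(y, g, length)
  if (any(ns < 2)) stop("every group needs >= 2 observations", call. = FALSE)
  means <- tapply(y, g, mean)
  df_res <- length(y) - k
  mse <- sum(tapply(y, g, function(v) sum((v - mean(v))^2))) / df_res
  ord <- order(means)
  rank_of <- match(seq_len(k), ord)
  pairs <- utils::combn(k, 2)
  res <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    d <- means[j] - means[i]
    se_t <- sqrt(mse * (1 / ns[i] + 1 / ns[j]))
    if (mse == 0) {
      p <- if (abs(d) == 0) 1 else 0
    } else if (method == "fisher_lsd") {
      p <- 2 * pt(abs(d) / se_t, df_res, lower.tail = FALSE)
    } else {
      q <- abs(d) / (se_t / sqrt(2)) # studentized range statistic
      span <- if (method == "tukey") k else abs(rank_of[i] - rank_of[j]) + 1
      p <- ptukey(q, span, df_res, lower.tail = FALSE)
    }
    c(diff = unname(d), p = unname(min(1, p)))
  })
  out <- data.frame(group1 = levels(g)[pairs[1, ]],
                    group2 = levels(g)[pairs[2, ]],
                    diff = res["diff", ], p = res["p", ])
  if (method == "newman_keuls") {
    # a pair can never be more significant than any ordered range
    # containing it
    lo <- pmin(rank_of[pairs[1, ]], rank_of[pairs[2, ]])
    hi <- pmax(rank_of[pairs[1, ]], rank_of[pairs[2, ]])
    for (idx in seq_len(ncol(pairs))) {
      contains <- lo <= lo[idx] & hi >= hi[idx]
      out$p[idx] <- max(out$p[contains])
    }
  }
  out$tier <- significance_tier(out$p)
  attr(out, "method") <- method
  rownames(out) <- NULL
  out
}

#' Significance tier letters
#'
#' Conventional tier labels for plots: `A` p < 0.05, `B` p < 0.01,
#' `C` p < 0.001, `D` p < 0.0001, empty otherwise.
#'
#' @param p Numeric vector of p values.
#' @return Character vector of tier letters.
#' @export
significance_tier <- function(p) {
  ifelse(p < 1e-4, "D",
         ifelse(p < 1e-3, "C",
                ifelse(p < 1e-2, "B",
                       ifelse(p < 0.05, "A", ""))))
}
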