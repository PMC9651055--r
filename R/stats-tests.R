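# Validation statistics: descriptives, distributional diagnostics,
# nonparametric group comparisons with post hoc tests, and rank
# correlations.  Established base-R / car routines are used wherever they
# exist; the Dunn post hoc test is computed from the mean-rank formula with
# tie-corrected variance because no installed package provides it.

test_result <- function(method, statistic, df, p_value, effect_size = NULL,
                        posthoc = NULL, note = NULL) {
  structure(list(method = method, statistic = unname(statistic),
                 df = unname(df), p_value = unname(p_value),
                 effect_size = effect_size, posthoc = posthoc, note = note),
            class = "sky_test_result")
}

#' @export
print.sky_test_result <- function(x, ...) {
  df_txt <- if (length(x$df) == 2)
    sprintf("(%.4g, %.4g)", x$df[1], x$df[2])
  else sprintf("(%.4g)", x$df)
  cat(sprintf("%s: statistic%s = %.4g, p = %.4g\n", x$method, df_txt,
              x$statistic, x$p_value))
  if (!is.null(x$effect_size))
    cat(sprintf("  effect size: %.4g\n", x$effect_size))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  if (!is.null(x$posthoc)) {
    cat("  post hoc (Bonferroni):\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}

#' Per-label summary statistics of EDB selection scores
#'
#' One row per semantic label with n, mean, SD, minimum, quartiles and
#' maximum of the label's EDB scores.  By default a label's summary uses
#' only the trials where the label was present on the image (`B_x > 0`,
#' via the `present_<label>` flags), which is why sample sizes differ
#' between labels.
#'
#' @param cbsv CBSV data frame from [build_cbsv()].
#' @param labels Labels to summarize (default: the vocabulary without
#'   `background`).
#' @param present_only Restrict each label's rows to trials where the label
#'   was available on the image (default `TRUE`; requires the
#'   `present_<label>` columns).
#' @return Data frame with columns `label`, `n`, `mean`, `sd`, `min`,
#'   `q25`, `median`, `q75`, `max`.
#' @export
describe_labels <- function(cbsv, labels = setdiff(SKY_LABELS, "background"),
                            present_only = TRUE) {
  stopifnot(nrow(cbsv) > 0)
  rows <- lapply(labels, function(lab) {
    x <- cbsv[[paste0("edb_", lab)]]
    pcol <- paste0("present_", lab)
    if (present_only && pcol %in% names(cbsv)) x <- x[cbsv[[pcol]]]
    if (length(x) == 0)
      return(data.frame(label = lab, n = 0L, mean = NA_real_, sd = NA_real_,
                        min = NA_real_, q25 = NA_real_, median = NA_real_,
                        q75 = NA_real_, max = NA_real_))
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(label = lab, n = length(x), mean = mean(x),
               sd = if (length(x) > 1) sd(x) else NA_real_,
               min = min(x), q25 = q[1], median = q[2], q75 = q[3],
               max = max(x))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-sample Kolmogorov-Smirnov normality test
#'
#' Tests the sample against a normal distribution with the sample's own
#' mean and SD.  Because the reference parameters are estimated from the
#' data the test is approximate (slightly conservative); the result carries
#' that caveat as a note.
#'
#' @param x Numeric vector, n >= 5, non-constant.
#' @return A test-result object with statistic D and p-value.
#' @export
ks_normality <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 5) stop("K-S normality test needs n >= 5", call. = FALSE)
  if (sd(x) == 0) stop("K-S normality test undefined for a zero-variance ",
                       "sample", call. = FALSE)
  kt <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
  test_result("Kolmogorov-Smirnov normality", kt$statistic, NA_real_,
              kt$p.value,
              note = "reference mean/sd estimated from the sample")
}

#' Levene test of homogeneity of variance
#'
#' Absolute deviations from the group centre (mean by default; median gives
#' the Brown-Forsythe variant) compared across groups.
#'
#' @param x Numeric outcome.
#' @param groups Grouping vector (>= 2 groups, each n >= 2).
#' @param center `"mean"` (default) or `"median"`.
#' @return A test-result object with the F statistic and its df.
#' @export
levene_test <- function(x, groups, center = c("mean", "median")) {
  center <- match.arg(center)
  g <- factor(groups)
  if (nlevels(g) < 2 || any(table(g) < 2))
    stop("Levene test needs >= 2 groups with >= 2 observations each",
         call. = FALSE)
  lt <- car::leveneTest(x, g, center = if (center == "mean") mean else median)
  test_result(sprintf("Levene (%s-centred)", center),
              lt[1, "F value"], c(lt[1, "Df"], lt[2, "Df"]),
              lt[1, "Pr(>F)"])
}

#' Welch one-way ANOVA with Bonferroni pairwise post hoc
#'
#' Welch-adjusted F with fractional denominator degrees of freedom (no
#' equal-variance assumption), classical eta-squared as effect size, and
#' pairwise Welch t comparisons with Bonferroni correction.
#'
#' @param x Numeric outcome.
#' @param groups Grouping vector (>= 2 groups).
#' @return A test-result object; `posthoc` holds the pairwise table.
#' @export
welch_anova <- function(x, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need >= 2 groups", call. = FALSE)
  if (all(tapply(x, g, function(v) var(v) == 0 || length(v) < 2)))
    stop("all groups have zero within-group variance", call. = FALSE)
  ft <- oneway.test(x ~ g, var.equal = FALSE)
  grand <- mean(x)
  ss_between <- sum(tapply(x, g, function(v) length(v) * (mean(v) - grand)^2))
  ss_total <- sum((x - grand)^2)
  ph <- pairwise.t.test(x, g, p.adjust.method = "bonferroni", pool.sd = FALSE)
  tab <- as.data.frame(as.table(ph$p.value), stringsAsFactors = FALSE)
  names(tab) <- c("group1", "group2", "p_adj")
  tab <- tab[!is.na(tab$p_adj), , drop = FALSE]
  rownames(tab) <- NULL
  test_result("Welch one-way ANOVA", ft$statistic,
              c(ft$parameter[["num df"]], ft$parameter[["denom df"]]),
              ft$p.value, effect_size = ss_between / ss_total, posthoc = tab)
}

#' Kruskal-Wallis rank-sum test
#'
#' H statistic with tie correction, df = k - 1, chi-square p-value.  When
#' every observation is identical H is defined as 0 (p = 1).
#'
#' @param x Numeric outcome.
#' @param groups Grouping vector (>= 2 groups).
#' @return A test-result object.
#' @export
kruskal_wallis <- function(x, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need >= 2 groups", call. = FALSE)
  if (length(unique(x)) == 1)
    return(test_result("Kruskal-Wallis", 0, nlevels(g) - 1, 1,
                       note = "all observations identical"))
  kt <- kruskal.test(x, g)
  test_result("Kruskal-Wallis", kt$statistic, kt$parameter, kt$p.value)
}

#' Dunn post hoc pairwise comparisons
#'
#' Pairwise z statistics from the groups' mean ranks with tie-corrected
#' variance, Bonferroni-adjusted over the m = k(k-1)/2 comparisons.
#' Degenerate pairs (zero variance and zero rank difference) yield z = 0.
#'
#' @param x Numeric outcome (same data the Kruskal-Wallis test ran on).
#' @param groups Grouping vector.
#' @return Data frame with one row per pair: `group1`, `group2`, `z`,
#'   `p_raw`, `p_adj`.
#' @export
dunn_posthoc <- function(x, groups) {
  g <- factor(groups)
  k <- nlevels(g)
  if (k < 2) stop("need >= 2 groups", call. = FALSE)
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tabulate(g)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  base_var <- N * (N + 1) / 12 - tie_corr
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  out <- data.frame(group1 = levels(g)[pairs[1, ]],
                    group2 = levels(g)[pairs[2, ]],
                    z = NA_real_, p_raw = NA_real_, p_adj = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se2 <- base_var * (1 / n[i1] + 1 / n[i2])
    diff <- rbar[[i1]] - rbar[[i2]]
    z <- if (se2 <= 0) 0 else diff / sqrt(se2)
    out$z[j] <- z
    out$p_raw[j] <- 2 * pnorm(-abs(z))
    out$p_adj[j] <- min(1, m * out$p_raw[j])
  }
  out
}

#' Spearman rank-correlation matrix
#'
#' Midrank-tie rank correlations on pairwise-complete observations, with
#' asymptotic p-values.  A constant column makes its correlations undefined:
#' the corresponding entries are `NA` and the pairs are listed in the
#' `"undefined"` attribute rather than silently reported as 0.
#'
#' @param data Data frame (or matrix) of numeric columns.
#' @param min_n Minimum complete observations per pair (default 3).
#' @return List with matrices `rho` and `p`, and attribute `"undefined"`.
#' @export
spearman_matrix <- function(data, min_n = 3) {
  data <- as.data.frame(data)
  p <- ncol(data)
  nms <- names(data)
  rho <- pval <- matrix(NA_real_, p, p, dimnames = list(nms, nms))
  diag(rho) <- 1; diag(pval) <- 0
  undefined <- character()
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      ok <- complete.cases(data[[i]], data[[j]])
      if (sum(ok) < min_n)
        stop(sprintf("pair (%s, %s) has fewer than %d complete observations",
                     nms[i], nms[j], min_n), call. = FALSE)
      xi <- data[[i]][ok]; xj <- data[[j]][ok]
      if (sd(xi) == 0 || sd(xj) == 0) {
        undefined <- c(undefined, paste(nms[i], nms[j], sep = ":"))
        next
      }
      ct <- suppressWarnings(cor.test(xi, xj, method = "spearman",
                                      exact = FALSE))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      pval[i, j] <- pval[j, i] <- ct$p.value
    }
  }
  structure(list(rho = rho, p = pval), undefined = undefined)
}
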