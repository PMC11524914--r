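# Group statistics over the feature table and per-participant curves:
# normality/variance-gated two-group tests, parallel-lines ANCOVA with
# Bonferroni post hoc contrasts, grand averages, and interval/band
# comparisons of connectivity curves.

#' Seven frequency ranges for band-wise coherence comparisons
#'
#' @return Named list partitioning 4-30 Hz: theta 4-8, low alpha 8-10,
#'   high alpha 10-13, low beta 13-16, middle beta 16-20, high beta 20-23,
#'   very high beta 23-30 Hz.
#' @export
comparison_bands <- function() {
  list(
    theta = c(4, 8), low_alpha = c(8, 10), high_alpha = c(10, 13),
    low_beta = c(13, 16), middle_beta = c(16, 20), high_beta = c(20, 23),
    very_high_beta = c(23, 30)
  )
}

# Normality gate shared by the two-group test and the ANCOVA: Shapiro-Wilk
# per group at alpha = 0.05; if any group rejects and all values are
# positive, analyse on the log scale (otherwise fall back, flagged).
normality_transform <- function(values, groups, alpha = 0.05) {
  ok <- is.finite(values)
  values <- values[ok]
  groups <- groups[ok]
  pvals <- vapply(split(values, groups), function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 3 || length(unique(v)) == 1 || length(v) > 5000) {
      return(1)
    }
    stats::shapiro.test(v)$p.value
  }, 0)
  reject <- any(pvals < alpha)
  if (reject && all(values > 0)) {
    list(values = log(values), groups = groups, transformed = TRUE,
         fallback = FALSE)
  } else {
    list(values = values, groups = groups, transformed = FALSE,
         fallback = reject)
  }
}

#' Two-group comparison of one feature
#'
#' Independent-sample comparison with the gating used throughout the
#' analysis: Shapiro-Wilk normality per group (log transform when
#' rejected and the data are positive), Levene's test for equal variance,
#' then a pooled t test or -- when Levene rejects -- Welch's t test,
#' two-sided.
#'
#' @param table Feature data frame.
#' @param variable Column to compare.
#' @param group_col Grouping column (default `main_group`).
#' @param groups Length-2 character: the two groups, in order.
#' @param alpha Gate level for the normality and variance tests.
#' @return One-row data frame (class `comparison_result`): variable,
#'   comparison, test used, statistic, df, p, adjusted p (NA here),
#'   transform flag, n per group.
#' @export
compare_two_groups <- function(table, variable, group_col = "main_group",
                               groups = c("HC", "MCI"), alpha = 0.05) {
  sel <- table[[group_col]] %in% groups
  v <- table[[variable]][sel]
  g <- factor(as.character(table[[group_col]][sel]), levels = groups)
  keep <- is.finite(v) & !is.na(g)
  v <- v[keep]
  g <- g[keep]
  if (min(table(g)) < 3) stop("need >= 3 observations per group")
  tr <- normality_transform(v, g, alpha)
  v <- tr$values
  g <- tr$groups
  lev_p <- if (stats::var(v) == 0) {
    1
  } else {
    car::leveneTest(v ~ g, center = mean)[1, "Pr(>F)"]
  }
  welch <- is.finite(lev_p) && lev_p < alpha
  tt <- stats::t.test(v ~ g, var.equal = !welch)
  data.frame(
    variable = variable,
    comparison = paste(groups, collapse = " vs "),
    test = if (welch) "Welch-t" else "t",
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p = tt$p.value,
    p_adj = NA_real_,
    transformed = tr$transformed,
    levene_p = unname(lev_p),
    n1 = sum(g == groups[1]), n2 = sum(g == groups[2]),
    stringsAsFactors = FALSE
  )
}

#' Covariate-adjusted group comparison (parallel-lines ANCOVA)
#'
#' Linear model `value ~ group + covariates` without group-by-covariate
#' interactions.  Reports the omnibus group effect (type II F) and, when
#' the grouping has more than two levels, all pairwise contrasts with
#' Bonferroni-adjusted p-values.  The same normality gate as
#' [compare_two_groups()] decides a log transform.
#'
#' @param table Feature data frame.
#' @param variable Column to analyse.
#' @param covariates Character vector of covariate columns (possibly
#'   empty, in which case the model collapses to a one-way comparison).
#' @param group_col Grouping column.
#' @param alpha Gate level for the normality check.
#' @return List with `omnibus` (one-row data frame) and `contrasts`
#'   (data frame of pairwise Bonferroni contrasts, or NULL for two
#'   groups).
#' @export
ancova_groups <- function(table, variable,
                          covariates = c("age", "sex", "education"),
                          group_col = "main_group", alpha = 0.05) {
  cols <- c(variable, group_col, covariates)
  miss <- setdiff(cols, names(table))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  d <- table[stats::complete.cases(table[cols]), cols]
  d <- d[is.finite(d[[variable]]), ]
  d$.group <- factor(as.character(d[[group_col]]))
  tr <- normality_transform(d[[variable]], d$.group, alpha)
  d$.y <- tr$values
  rhs <- paste(c(".group", covariates), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = d)
  if (fit$rank < length(fit$coefficients)) stop("rank-deficient design")
  an <- car::Anova(fit, type = 2)
  row <- which(rownames(an) == ".group")
  omnibus <- data.frame(
    variable = variable,
    comparison = paste(levels(d$.group), collapse = "/"),
    test = "ANCOVA",
    statistic = an[row, "F value"],
    df = an[row, "Df"],
    p = an[row, "Pr(>F)"],
    p_adj = NA_real_,
    transformed = tr$transformed,
    covariates = paste(covariates, collapse = "+"),
    stringsAsFactors = FALSE
  )
  contrasts <- NULL
  if (nlevels(d$.group) > 2) {
    em <- emmeans::emmeans(fit, ".group")
    ct <- as.data.frame(
      emmeans::contrast(em, method = "pairwise", adjust = "bonferroni")
    )
    raw <- as.data.frame(
      emmeans::contrast(em, method = "pairwise", adjust = "none")
    )
    contrasts <- data.frame(
      contrast = as.character(ct$contrast),
      estimate = ct$estimate,
      statistic = ct$t.ratio,
      p = raw$p.value,
      p_adj = ct$p.value,
      stringsAsFactors = FALSE
    )
  }
  list(omnibus = omnibus, contrasts = contrasts)
}

#' Group-mean (grand average) curves
#'
#' Pointwise mean of per-participant curves within each group; for ERP
#' input the two-channel mean should be formed first.
#'
#' @param curves Numeric matrix `[participants x points]`.
#' @param grouping Factor/character vector, one label per row.
#' @return Matrix `[groups x points]` with group labels as row names.
#' @export
grand_average_curves <- function(curves, grouping) {
  curves <- as.matrix(curves)
  if (nrow(curves) != length(grouping)) stop("one group label per curve")
  g <- factor(grouping)
  out <- t(vapply(levels(g), function(lv) {
    colMeans(curves[g == lv, , drop = FALSE])
  }, numeric(ncol(curves))))
  rownames(out) <- levels(g)
  out
}

#' Interval-wise comparison of PLV curves between two groups
#'
#' Per participant, the curve is averaged within consecutive 100 ms
#' intervals over 0-700 ms (seven intervals); each interval mean is then
#' compared between groups with the gated t/Welch test.  A pointwise
#' per-sample mask (uncorrected, alpha = 0.05) accompanies the interval
#' results.
#'
#' @param curves Matrix `[participants x time]` of PLV values.
#' @param time Time axis in ms.
#' @param grouping Group label per participant (two levels).
#' @param intervals List of `[lo, hi)` intervals in ms; default seven
#'   100 ms bins over 0-700 ms.
#' @param alpha Pointwise significance level.
#' @return List with `intervals` (data frame, one row per interval),
#'   `mask` (logical per sample), `p_pointwise`.
#' @export
interval_comparison <- function(curves, time, grouping, intervals = NULL,
                                alpha = 0.05) {
  if (is.null(intervals)) {
    intervals <- lapply(0:6, function(i) c(i * 100, (i + 1) * 100))
    names(intervals) <- vapply(intervals,
                               function(w) paste0(w[1], "-", w[2], "ms"), "")
  }
  curves <- as.matrix(curves)
  g <- factor(grouping)
  stopifnot(nlevels(g) == 2, nrow(curves) == length(g))
  rows <- lapply(names(intervals), function(nm) {
    idx <- window_idx(time, intervals[[nm]])
    if (!length(idx)) stop("interval ", nm, " outside the curve")
    m <- rowMeans(curves[, idx, drop = FALSE])
    d <- data.frame(y = m, main_group = g)
    r <- compare_two_groups(d, "y", groups = levels(g))
    r$variable <- nm
    r$n_samples <- length(idx)
    r
  })
  p_point <- apply(curves, 2, function(v) {
    stats::t.test(v[g == levels(g)[1]], v[g == levels(g)[2]])$p.value
  })
  list(
    intervals = do.call(rbind, rows),
    mask = p_point < alpha,
    p_pointwise = p_point
  )
}

#' Band-wise comparison of coherence spectra between two groups
#'
#' Analogous to [interval_comparison()] on the frequency axis: per
#' participant band means over the seven named ranges, gated two-group
#' test per band, plus an uncorrected per-bin mask.
#'
#' @param spectra Matrix `[participants x freq bins]` of coherence.
#' @param freq Frequency axis in Hz.
#' @param grouping Group label per participant (two levels).
#' @param bands Named list of `[lo, hi)` ranges; default
#'   [comparison_bands()].
#' @param alpha Pointwise significance level.
#' @return List with `bands` (data frame), `mask`, `p_pointwise`.
#' @export
band_comparison <- function(spectra, freq, grouping,
                            bands = comparison_bands(), alpha = 0.05) {
  spectra <- as.matrix(spectra)
  g <- factor(grouping)
  stopifnot(nlevels(g) == 2, nrow(spectra) == length(g))
  rows <- lapply(names(bands), function(nm) {
    idx <- which(freq >= bands[[nm]][1] & freq < bands[[nm]][2])
    if (!length(idx)) stop("band ", nm, " contains no bins")
    m <- rowMeans(spectra[, idx, drop = FALSE])
    d <- data.frame(y = m, main_group = g)
    r <- compare_two_groups(d, "y", groups = levels(g))
    r$variable <- nm
    r$n_bins <- length(idx)
    r
  })
  p_point <- apply(spectra, 2, function(v) {
    stats::t.test(v[g == levels(g)[1]], v[g == levels(g)[2]])$p.value
  })
  list(
    bands = do.call(rbind, rows),
    mask = p_point < alpha,
    p_pointwise = p_point
  )
}
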