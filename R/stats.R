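# Population-level statistical workflow for trait tables: one row per
# seed/variety, one column per trait or index, optional group labels.

.numeric_cols <- function(t) {
  x <- as.data.frame(t)
  x[vapply(x, is.numeric, logical(1))]
}

#' Descriptive statistics per trait
#'
#' Mean, sample SD (n - 1 denominator), coefficient of variation
#' (SD / mean) and range per numeric column.
#'
#' @param t data.frame of traits (numeric columns are summarised).
#' @return data.frame with columns `trait`, `n`, `mean`, `sd`, `cv`,
#'   `min`, `max`. A zero mean with nonzero SD yields `cv = NA`.
#' @export
describe <- function(t) {
  x <- .numeric_cols(t)
  if (nrow(x) < 2) stop("need at least 2 rows")
  res <- lapply(names(x), function(nm) {
    v <- x[[nm]]
    m <- mean(v); s <- sd(v)
    cv <- if (s == 0) 0 else if (m == 0) NA_real_ else s / m
    data.frame(trait = nm, n = length(v), mean = m, sd = s, cv = cv,
               min = min(v), max = max(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Pearson correlation matrix with significance
#'
#' Pairwise Pearson r with two-sided p-values from the t transform
#' `t = r sqrt((n-2)/(1-r^2))`, and significance stars at 0.05 / 0.01 /
#' 0.001. Constant columns yield NA entries.
#'
#' @param t data.frame of traits.
#' @return List with matrices `r`, `p` and character matrix `stars`.
#' @export
pearson_matrix <- function(t) {
  x <- .numeric_cols(t)
  n <- nrow(x)
  if (n < 3) stop("need at least 3 rows")
  keep_sd <- vapply(x, sd, numeric(1))
  r <- suppressWarnings(cor(as.matrix(x)))
  r[keep_sd == 0, ] <- NA
  r[, keep_sd == 0] <- NA
  diag(r)[keep_sd > 0] <- 1
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * pt(-abs(tt), df = n - 2)
  diag(p) <- NA
  stars <- matrix("", nrow(r), ncol(r), dimnames = dimnames(r))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  stars[!is.na(p) & p < 0.001] <- "***"
  list(r = r, p = p, stars = stars)
}

#' Z-score standardisation
#'
#' Centres each numeric column to mean 0 and scales to sample SD 1.
#'
#' @param t data.frame of traits.
#' @return data.frame of the same shape with standardised numeric columns.
#' @export
zscore <- function(t) {
  x <- as.data.frame(t)
  if (nrow(x) < 2) stop("need at least 2 rows (SD undefined)")
  for (nm in names(x)) {
    if (!is.numeric(x[[nm]])) next
    s <- sd(x[[nm]])
    if (s == 0) stop(sprintf("constant column '%s' cannot be standardised", nm))
    x[[nm]] <- (x[[nm]] - mean(x[[nm]])) / s
  }
  x
}

#' Ward hierarchical clustering on squared Euclidean distances
#'
#' Classic Ward criterion: agglomerative merges minimising the increase in
#' within-cluster sum of squared error, computed on squared Euclidean
#' distances of the (caller-standardised) trait rows. Merge heights are
#' reported as the SSE increase of each merge.
#'
#' @param t data.frame or matrix of (standardised) traits.
#' @param k number of clusters for the reported cut (1 <= k <= rows).
#' @return List with `merge` (hclust merge matrix), `delta_sse` (SSE
#'   increase per merge), `labels` (cluster id per row for the k-cut),
#'   `sse` (total within-cluster SSE at the cut) and the underlying
#'   `hclust` object.
#' @export
ward_cluster <- function(t, k = 3L) {
  x <- as.matrix(.numeric_cols(t))
  n <- nrow(x)
  if (k < 1 || k > n) stop("k must be between 1 and the number of rows")
  if (n == 1) {
    return(list(merge = matrix(numeric(0), 0, 2), delta_sse = numeric(0),
                labels = 1L, sse = 0, hclust = NULL))
  }
  d2 <- stats::as.dist(as.matrix(dist(x))^2)
  hc <- hclust(d2, method = "ward.D")
  labels <- cutree(hc, k = k)
  sse <- 0
  for (g in unique(labels)) {
    xs <- x[labels == g, , drop = FALSE]
    sse <- sse + sum(sweep(xs, 2, colMeans(xs))^2)
  }
  list(merge = hc$merge, delta_sse = hc$height / 2, labels = labels,
       sse = sse, hclust = hc)
}

# Compact letter display (insert-and-absorb): groups ordered by decreasing
# mean share a letter iff no significant difference separates them.
.letter_display <- function(sig, means) {
  g <- length(means)
  ord <- order(-means)
  cols <- list(ord)  # start: one column containing all groups
  pairs <- which(sig, arr.ind = TRUE)
  pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
  for (pi in seq_len(nrow(pairs))) {
    i <- pairs[pi, 1]; j <- pairs[pi, 2]
    newcols <- list()
    for (cc in cols) {
      if (i %in% cc && j %in% cc) {
        newcols <- c(newcols, list(setdiff(cc, i)), list(setdiff(cc, j)))
      } else newcols <- c(newcols, list(cc))
    }
    # absorb columns that are subsets of others
    keep <- rep(TRUE, length(newcols))
    for (a in seq_along(newcols)) for (b in seq_along(newcols)) {
      if (a != b && keep[a] && keep[b] &&
          all(newcols[[a]] %in% newcols[[b]])) keep[a] <- FALSE
    }
    cols <- newcols[keep]
  }
  # order columns by best (highest-mean) member, assign letters
  first <- vapply(cols, function(cc) min(match(cc, ord)), numeric(1))
  cols <- cols[order(first)]
  lets <- rep("", g)
  for (ci in seq_along(cols))
    for (m in cols[[ci]]) lets[m] <- paste0(lets[m], letters[ci])
  lets
}

#' One-way ANOVA with LSD or Bonferroni pairwise comparison
#'
#' For each numeric trait column: one-way ANOVA across groups; per-group
#' Shapiro-Wilk normality check at 0.05 (groups with fewer than 3 values
#' cannot be tested and count as normal). When all groups are normal,
#' pairwise comparisons use Fisher's LSD (t tests on the pooled ANOVA
#' mean square error); otherwise Bonferroni-adjusted pairwise t tests are
#' used to avoid false positives. Groups sharing no letter differ at
#' P < 0.05.
#'
#' @param t data.frame of traits.
#' @param groups factor/vector of group labels, one per row (>= 2 groups,
#'   each with >= 2 rows).
#' @param alpha significance level for the letter display.
#' @return Named list per trait: `F`, `p`, `method` ("LSD" or
#'   "Bonferroni"), `means`, `letters`, `pairwise` (p-value matrix).
#' @export
group_compare <- function(t, groups, alpha = 0.05) {
  x <- .numeric_cols(t)
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("every group needs at least 2 rows")
  ng <- nlevels(g)
  out <- list()
  for (nm in names(x)) {
    y <- x[[nm]]
    fit <- aov(y ~ g)
    an <- summary(fit)[[1]]
    Fv <- an$`F value`[1]
    pv <- an$`Pr(>F)`[1]
    mse <- an$`Mean Sq`[2]
    dfe <- an$Df[2]
    means <- tapply(y, g, mean)
    ns <- tapply(y, g, length)
    normal <- all(vapply(levels(g), function(lv) {
      yy <- y[g == lv]
      if (length(yy) < 3 || sd(yy) == 0) TRUE
      else shapiro.test(yy)$p.value >= 0.05
    }, logical(1)))
    pm <- matrix(NA_real_, ng, ng, dimnames = list(levels(g), levels(g)))
    npair <- ng * (ng - 1) / 2
    for (i in seq_len(ng - 1)) for (j in (i + 1):ng) {
      se <- sqrt(mse * (1 / ns[i] + 1 / ns[j]))
      tv <- (means[i] - means[j]) / se
      p0 <- 2 * pt(-abs(tv), dfe)
      pm[i, j] <- pm[j, i] <- if (normal) p0 else min(1, p0 * npair)
    }
    sig <- !is.na(pm) & pm < alpha
    out[[nm]] <- list(F = Fv, p = pv,
                      method = if (normal) "LSD" else "Bonferroni",
                      means = means,
                      letters = setNames(.letter_display(sig, means),
                                         levels(g)),
                      pairwise = pm)
  }
  out
}

#' Linear trend across ordered periods
#'
#' Ordinary least squares of trait means on period codes, with R² and the
#' percent change from the first to the last period.
#'
#' @param x numeric period codes (>= 3 points).
#' @param y trait means per period.
#' @return List with `slope`, `intercept`, `r_squared`, `pct_change`.
#' @export
trend_fit <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3) stop("need at least 3 points")
  fit <- lm(y ~ x)
  r2 <- if (sd(y) == 0) 0
        else suppressWarnings(summary(fit)$r.squared)  # exact fits are fine
  ord <- order(x)
  y0 <- y[ord][1]
  y1 <- y[ord][length(y)]
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2, pct_change = (y1 - y0) / y0 * 100)
}

#' Agreement between two measurement series
#'
#' Coefficient of determination (R²) of the least-squares fit of `y`
#' (e.g. CT-extracted) on `x` (e.g. manual measurements).
#'
#' @param x,y paired numeric vectors of equal length >= 3.
#' @return R² in \[0, 1\].
#' @export
agreement <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3) stop("need at least 3 points")
  suppressWarnings(summary(lm(y ~ x))$r.squared)  # exact fits are fine
}
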