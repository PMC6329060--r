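# Reliability statistics: ANOVA-based intraclass correlation coefficients
# (interobserver ICC(2,1) absolute agreement, intraobserver ICC(3,1)
# consistency, Shrout-Fleiss / McGraw-Wong conventions) and the cohort
# comparison battery (normality, variance homogeneity, t test, Pearson r).

#' Build a ratings table
#'
#' @param data data frame in long format with columns `subject`, `rater`,
#'   `session`, `pi_deg` (or supply a different `value` column name).
#' @param value name of the measurement column (default `"pi_deg"`).
#' @return An object of class `ratings_table`: a 3-d array
#'   subjects x raters x sessions.
#' @export
ratings_table <- function(data, value = "pi_deg") {
  req <- c("subject", "rater", "session", value)
  missing <- setdiff(req, names(data))
  if (length(missing) > 0)
    stop("ratings data is missing columns: ", paste(missing, collapse = ", "))
  subj <- sort(unique(data$subject))
  raters <- sort(unique(data$rater))
  sessions <- sort(unique(data$session))
  arr <- array(NA_real_,
               dim = c(length(subj), length(raters), length(sessions)),
               dimnames = list(subject = as.character(subj),
                               rater = as.character(raters),
                               session = as.character(sessions)))
  idx <- cbind(match(data$subject, subj), match(data$rater, raters),
               match(data$session, sessions))
  if (anyDuplicated(idx) > 0)
    stop("duplicated (subject, rater, session) cells in the ratings data")
  arr[idx] <- data[[value]]
  if (anyNA(arr))
    stop("incomplete crossed design: every subject x rater x session cell ",
         "must be present")
  if (any(!is.finite(arr))) stop("non-finite measurement values")
  structure(arr, class = "ratings_table")
}

# two-way ANOVA mean squares for a subjects x raters matrix
anova_mean_squares <- function(M) {
  n <- nrow(M); k <- ncol(M)
  grand <- mean(M)
  row_m <- rowMeans(M)
  col_m <- colMeans(M)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((M - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  list(msr = msr, msc = msc, mse = mse, n = n, k = k)
}

icc_degenerate <- function(M) {
  isTRUE(all.equal(max(M) - min(M), 0)) ||
    anova_mean_squares(M)$msr < .Machine$double.eps
}

#' Interobserver ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC from
#' the two-way ANOVA decomposition:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`, with the F-based
#' 95% confidence interval of McGraw & Wong. When the table has multiple
#' sessions, each rater's sessions are averaged first (documented choice).
#'
#' @param table a [ratings_table()] (or a subjects x raters matrix).
#' @param conf confidence level (default 0.95).
#' @return A list with `icc`, `ci` (length 2), `mean_squares`, `n`, `k`.
#' @export
icc_interobserver <- function(table, conf = 0.95) {
  M <- ratings_matrix(table)
  n <- nrow(M); k <- ncol(M)
  if (k < 2) stop("need at least 2 raters")
  if (n < 5) stop("need at least 5 subjects, got ", n)
  if (icc_degenerate(M)) {
    warning("degenerate ratings (no variance); ICC defined as 1")
    return(list(icc = 1, ci = c(1, 1), mean_squares = anova_mean_squares(M),
                n = n, k = k))
  }
  ms <- anova_mean_squares(M)
  icc <- (ms$msr - ms$mse) /
    (ms$msr + (k - 1) * ms$mse + k * (ms$msc - ms$mse) / n)
  alpha <- 1 - conf
  fj <- ms$msc / ms$mse
  vn <- (k - 1) * (n - 1) *
    (k * icc * fj + n * (1 + (k - 1) * icc) - k * icc)^2
  vd <- (n - 1) * k^2 * icc^2 * fj^2 +
    (n * (1 + (k - 1) * icc) - k * icc)^2
  v <- vn / vd
  fl <- qf(1 - alpha / 2, n - 1, v)
  fu <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (ms$msr - fl * ms$mse) /
    (fl * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
  upper <- n * (fu * ms$msr - ms$mse) /
    (k * ms$msc + (k * n - k - n) * ms$mse + n * fu * ms$msr)
  list(icc = icc, ci = c(lower, upper), mean_squares = ms, n = n, k = k)
}

ratings_matrix <- function(table) {
  if (inherits(table, "ratings_table")) {
    arr <- unclass(table)
    if (length(dim(arr)) == 3) {
      if (dim(arr)[3] > 1) apply(arr, c(1, 2), mean) else arr[, , 1]
    } else arr
  } else as.matrix(table)
}

#' Intraobserver ICC(3,1)
#'
#' Two-way mixed-effects, consistency, single-measurement ICC over one
#' rater's sessions: `(MSR - MSE) / (MSR + (k-1) MSE)` with the exact
#' F-based confidence interval. With `rater = NULL`, per-rater ICCs are
#' returned together with their unweighted mean as the pooled summary.
#'
#' @param table a [ratings_table()] with >= 2 sessions.
#' @param rater rater name or index; `NULL` for all raters.
#' @param conf confidence level (default 0.95).
#' @return For a single rater: a list with `icc`, `ci`, `mean_squares`,
#'   `n`, `k`. For all raters: a list with `per_rater` (named list),
#'   `icc_mean` and `icc_range`.
#' @export
icc_intraobserver <- function(table, rater = NULL, conf = 0.95) {
  stopifnot(inherits(table, "ratings_table"))
  arr <- unclass(table)
  if (length(dim(arr)) != 3 || dim(arr)[3] < 2)
    stop("need at least 2 sessions per rater")
  raters <- dimnames(arr)$rater
  one <- function(rr) {
    M <- arr[, rr, ]                   # subjects x sessions
    n <- nrow(M); k <- ncol(M)
    if (icc_degenerate(M)) {
      warning("degenerate ratings (no variance); ICC defined as 1")
      return(list(icc = 1, ci = c(1, 1),
                  mean_squares = anova_mean_squares(M), n = n, k = k))
    }
    ms <- anova_mean_squares(M)
    icc <- (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse)
    alpha <- 1 - conf
    f <- ms$msr / ms$mse
    fl <- f / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- f * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    list(icc = icc,
         ci = c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1)),
         mean_squares = ms, n = n, k = k)
  }
  if (!is.null(rater)) return(one(rater))
  per <- setNames(lapply(raters, one), raters)
  iccs <- vapply(per, `[[`, 0, "icc")
  list(per_rater = per, icc_mean = mean(iccs), icc_range = range(iccs))
}

# Levene's test (mean-centered, classic form) for two groups
levene_test <- function(a, b) {
  za <- abs(a - mean(a))
  zb <- abs(b - mean(b))
  g <- factor(rep(c("a", "b"), c(length(a), length(b))))
  z <- c(za, zb)
  n <- length(z)
  zg <- tapply(z, g, mean)
  grand <- mean(z)
  ssb <- sum(table(g) * (zg - grand)^2)
  ssw <- sum((z - zg[g])^2)
  df1 <- 1
  df2 <- n - 2
  f <- (ssb / df1) / (ssw / df2)
  list(statistic = f, p.value = pf(f, df1, df2, lower.tail = FALSE))
}

#' Compare PI between two cohorts
#'
#' Per-group normality check (Kolmogorov-Smirnov against a normal with the
#' sample moments), Levene variance-homogeneity test, then a pooled- or
#' separate-variance t test accordingly; optionally the Pearson correlation
#' of the pooled values against a covariate (e.g. age).
#'
#' @param values_a,values_b PI values (degrees) of the two groups, n >= 3
#'   each.
#' @param covariate optional numeric covariate, length
#'   `length(values_a) + length(values_b)`, for the Pearson correlation.
#' @param alpha significance level driving the pooled/separate choice
#'   (default 0.05).
#' @return A list with `normality` (per-group KS results), `levene`,
#'   `t_test` (including `pooled`, logical), and optionally `pearson`.
#' @export
cohort_compare <- function(values_a, values_b, covariate = NULL,
                           alpha = 0.05) {
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (length(a) < 3 || length(b) < 3)
    stop("each group needs at least 3 values")
  ks <- function(x) {
    if (sd(x) == 0) return(list(statistic = NA_real_, p.value = NA_real_))
    res <- suppressWarnings(ks.test(x, "pnorm", mean = mean(x), sd = sd(x)))
    list(statistic = unname(res$statistic), p.value = res$p.value)
  }
  lev <- levene_test(a, b)
  pooled <- !is.na(lev$p.value) && lev$p.value >= alpha
  tt <- if (isTRUE(all.equal(a, b))) {
    list(statistic = 0, p.value = 1, df = length(a) + length(b) - 2)
  } else {
    res <- stats::t.test(a, b, var.equal = pooled)
    list(statistic = unname(res$statistic), p.value = res$p.value,
         df = unname(res$parameter))
  }
  out <- list(normality = list(a = ks(a), b = ks(b)),
              levene = lev,
              t_test = c(tt, list(pooled = pooled)),
              mean_a = mean(a), sd_a = sd(a), n_a = length(a),
              mean_b = mean(b), sd_b = sd(b), n_b = length(b))
  if (!is.null(covariate)) {
    x <- c(a, b)
    if (length(covariate) != length(x))
      stop("covariate length must equal the pooled group size")
    ct <- suppressWarnings(cor.test(x, covariate, method = "pearson"))
    out$pearson <- list(r = unname(ct$estimate), p.value = ct$p.value)
  }
  out
}

#' Simulate a complete ratings table
#'
#' Subjects are drawn from `N(mean, subject_sd^2)`; each rating adds
#' independent `N(0, error_sd^2)` noise plus optional per-rater fixed
#' offsets. Used by the reliability recovery tests.
#'
#' @param n_subjects,n_raters,n_sessions design size.
#' @param mean,subject_sd,error_sd variance components (degrees).
#' @param rater_offsets optional length-`n_raters` fixed shifts.
#' @return A [ratings_table()].
#' @export
simulate_ratings <- function(n_subjects = 30, n_raters = 3, n_sessions = 2,
                             mean = 45, subject_sd = 8, error_sd = 1,
                             rater_offsets = rep(0, n_raters)) {
  subj <- rnorm(n_subjects, mean, subject_sd)
  arr <- array(NA_real_, dim = c(n_subjects, n_raters, n_sessions),
               dimnames = list(subject = seq_len(n_subjects),
                               rater = paste0("R", seq_len(n_raters)),
                               session = seq_len(n_sessions)))
  for (r in seq_len(n_raters))
    for (s in seq_len(n_sessions))
      arr[, r, s] <- subj + rater_offsets[r] +
        rnorm(n_subjects, 0, error_sd)
  structure(arr, class = "ratings_table")
}
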