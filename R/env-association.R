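# Environmental association of presence status: per-factor t tests, the
# subsampling permutation null, and the collinearity pre-filter used before
# ordination.

#' Per-factor two-group comparison of climate variables
#'
#' Two-sided equal-variance Student's t test per factor between the
#' present-group and absent-group accessions, with a Benjamini-Hochberg
#' adjusted column reported alongside the raw p-values. Factors with fewer
#' than two non-missing values in either group are skipped with a warning.
#'
#' @param env data.frame with an `accession` column plus numeric climate
#'   factor columns (e.g. `bio1`..`bio19`).
#' @param present,absent character vectors of accession ids in the two
#'   groups.
#' @param factors factor columns to test; defaults to every `bio*` column.
#' @return data.frame with one row per tested factor: group sizes and means,
#'   `mean_diff` (absent minus present), `t`, `p`, `p_adj`.
#' @export
ttest_env <- function(env, present, absent,
                      factors = grep("^bio", names(env), value = TRUE)) {
  stopifnot("accession" %in% names(env), length(factors) > 0L)
  if (anyDuplicated(env$accession)) stop("duplicated accession ids in the table")
  pres <- env[env$accession %in% present, , drop = FALSE]
  abs_ <- env[env$accession %in% absent, , drop = FALSE]
  rows <- list()
  for (f in factors) {
    x <- pres[[f]][!is.na(pres[[f]])]
    y <- abs_[[f]][!is.na(abs_[[f]])]
    if (length(x) < 2L || length(y) < 2L) {
      warning("factor '", f, "' has fewer than 2 values in a group; skipped")
      next
    }
    if (stats::sd(c(x, y)) == 0) {
      tt <- list(statistic = 0, p.value = 1)
    } else {
      tt <- stats::t.test(y, x, var.equal = TRUE)
    }
    rows[[f]] <- data.frame(factor = f, n_present = length(x), n_absent = length(y),
                            mean_present = mean(x), mean_absent = mean(y),
                            mean_diff = mean(y) - mean(x),
                            t = unname(tt$statistic), p = tt$p.value,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable factors")
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Subsampling permutation test of a group mean
#'
#' Draws `n_perm` subsamples of size `length(absent)` from the present-group
#' values (without replacement by default), records each subsample mean as
#' the null distribution, and compares the observed absent-group mean to the
#' empirical 2.5th/97.5th percentiles. The test is significant when the
#' observed mean falls outside that interval. The empirical p-value uses the
#' plus-one rule `(1 + 2 * min(#null <= obs, #null >= obs)) / (n_perm + 1)`,
#' capped at 1, and can therefore never be exactly 0.
#'
#' With `statistic = "diff"` the null statistic is instead the difference
#' between the subsample mean and the mean of the remaining present values,
#' and the observed statistic is `mean(absent) - mean(present)`.
#'
#' @param present,absent numeric value vectors for the two groups;
#'   `length(present)` must exceed `length(absent)`.
#' @param n_perm number of permutations.
#' @param seed optional integer seed (stored in the result).
#' @param statistic `"mean"` (default) or `"diff"`.
#' @param replace draw with replacement instead of without.
#' @param conf_level confidence level of the percentile interval.
#' @return an object of class `permutation_test` with fields
#'   `observed_mean`, `null_means`, `ci_low`, `ci_high`, `p_empirical`,
#'   `significant`, `seed`, `statistic`, `n_perm`.
#' @export
permutation_test <- function(present, absent, n_perm = 1000L, seed = NULL,
                             statistic = c("mean", "diff"), replace = FALSE,
                             conf_level = 0.95) {
  statistic <- match.arg(statistic)
  present <- present[!is.na(present)]
  absent <- absent[!is.na(absent)]
  k <- length(absent)
  n <- length(present)
  if (k < 1L) stop("absent group is empty")
  if (!replace && k > n) stop("subsample size exceeds the present group size")
  if (n <= k) stop("present group must be larger than the absent group")
  null_means <- with_seed(seed, {
    if (statistic == "mean") {
      vapply(seq_len(n_perm), function(i)
        mean(present[sample.int(n, k, replace = replace)]), numeric(1))
    } else {
      vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(n, k, replace = replace)
        mean(present[idx]) - mean(present[-unique(idx)])
      }, numeric(1))
    }
  })
  obs <- if (statistic == "mean") mean(absent) else mean(absent) - mean(present)
  alpha <- (1 - conf_level) / 2
  ci <- unname(stats::quantile(null_means, c(alpha, 1 - alpha)))
  p <- min(1, (1 + 2 * min(sum(null_means <= obs), sum(null_means >= obs))) /
             (n_perm + 1))
  structure(list(observed_mean = obs, null_means = null_means,
                 ci_low = ci[1], ci_high = ci[2], p_empirical = p,
                 significant = obs < ci[1] || obs > ci[2],
                 seed = seed, statistic = statistic, n_perm = n_perm),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat("Subsampling permutation test (", x$n_perm, " draws, statistic = ",
      x$statistic, ")\n", sep = "")
  cat(sprintf("  observed: %.4g  null 95%% interval: [%.4g, %.4g]\n",
              x$observed_mean, x$ci_low, x$ci_high))
  cat(sprintf("  empirical p: %.4g  significant: %s\n",
              x$p_empirical, x$significant))
  invisible(x)
}

#' Greedy collinearity filter for climate factors
#'
#' While any factor pair has an absolute Pearson correlation above the
#' threshold, drops the factor with the largest mean absolute correlation to
#' all remaining factors (ties broken deterministically by column order).
#' Zero-variance factors are dropped first with a warning. Correlations are
#' computed on pairwise-complete observations.
#'
#' @param env data.frame of accessions by factors (an `accession` column, if
#'   present, is ignored).
#' @param threshold absolute correlation above which a pair is collinear.
#' @param factors factor columns to consider; defaults to every `bio*`
#'   column, falling back to all numeric columns.
#' @return character vector of retained factor names, with the dropped ones
#'   in attribute `"dropped"`.
#' @export
filter_collinear <- function(env, threshold = 0.7,
                             factors = grep("^bio", names(env), value = TRUE)) {
  if (length(factors) == 0L)
    factors <- names(env)[vapply(env, is.numeric, logical(1))]
  if (length(factors) < 2L) stop("need at least two factors")
  x <- env[, factors, drop = FALSE]
  if (nrow(x) < 3L) stop("need at least three accessions")
  dropped <- character(0)
  const <- vapply(x, function(v) stats::sd(v, na.rm = TRUE) == 0 ||
                    all(is.na(v)), logical(1))
  if (any(const)) {
    warning("dropping zero-variance factor(s): ",
            paste(factors[const], collapse = ", "))
    dropped <- factors[const]
    factors <- factors[!const]
    x <- x[, factors, drop = FALSE]
  }
  repeat {
    if (length(factors) < 2L) break
    r <- abs(stats::cor(x, use = "pairwise.complete.obs"))
    diag(r) <- 0
    if (max(r, na.rm = TRUE) <= threshold) break
    mean_abs <- rowMeans(r, na.rm = TRUE)
    worst <- which.max(mean_abs)  # first max = earliest column, tie-break
    dropped <- c(dropped, factors[worst])
    factors <- factors[-worst]
    x <- x[, factors, drop = FALSE]
  }
  structure(factors, dropped = dropped)
}
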