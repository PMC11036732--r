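#' Mean and sample SD with NaN exclusion
#'
#' Summary used for every "Mean (+/- SD)" table row: `NaN`/`NA` entries
#' (subjects without blinks in a category) are excluded, the SD is the
#' sample (n-1) form, and the number of values actually used is reported.
#'
#' @param values numeric vector, `NaN`/`NA` allowed.
#' @return List with `mean`, `sd`, `n_used`.
#' @export
group_mean_sd <- function(values) {
  v <- values[is.finite(values)]
  if (!length(v))
    gtr_stop("all values are NaN/NA: empty group", "gtr_empty_group_error")
  list(mean = mean(v), sd = if (length(v) > 1L) sd(v) else 0, n_used = length(v))
}

#' Per-tap group-average table
#'
#' Builds the per-tap cohort table: for each tap ordinal, group and
#' category, the mean over the group's subjects of that subject's blink
#' count at the tap. Subjects with fewer detected taps than the ordinal are
#' excluded from that cell's denominator. A mean/SD row over the per-tap
#' cells is appended per column.
#'
#' @param records list of `gtr_subject` objects.
#' @param n_taps number of tap ordinals to tabulate (default 8).
#' @return List with `cells` (`data.frame` of `tap, group, category, value`)
#'   and `mean_sd` (`data.frame` of `group, category, mean, sd`).
#' @export
tap_average_table <- function(records, n_taps = 8L) {
  if (!length(records)) gtr_stop("no subject records", "gtr_empty_group_error")
  groups <- unique(vapply(records, function(r) r$group, character(1)))
  cells <- expand.grid(tap = seq_len(n_taps), group = groups,
                       category = c("reflex", "non_reflex"),
                       stringsAsFactors = FALSE)
  cells$value <- NA_real_
  for (i in seq_len(nrow(cells))) {
    k <- cells$tap[i]
    vals <- unlist(lapply(records, function(r) {
      if (r$group != cells$group[i] || nrow(r$tapwise) < k) return(NULL)
      if (cells$category[i] == "reflex") r$tapwise$reflex_count[k]
      else r$tapwise$non_reflex_count[k]
    }))
    cells$value[i] <- if (length(vals)) mean(vals) else NA_real_
  }
  mean_sd <- do.call(rbind, lapply(split(cells, list(cells$group, cells$category)),
    function(d) {
      g <- group_mean_sd(d$value)
      data.frame(group = d$group[1], category = d$category[1],
                 mean = g$mean, sd = g$sd)
    }))
  rownames(mean_sd) <- NULL
  list(cells = cells, mean_sd = mean_sd)
}

# Exact null distribution of the rank-sum of a size-m subset of the pooled
# midranks, by subset-sum dynamic programming over doubled midranks (doubling
# makes midranks integral even with ties). Returns P(W <= w) and P(W >= w).
rank_sum_exact_tails <- function(ranks2, m, w2) {
  N <- length(ranks2)
  maxsum <- sum(ranks2)
  # f[k+1, s+1] = number of size-k subsets with doubled-rank sum s
  f <- matrix(0, nrow = m + 1L, ncol = maxsum + 1L)
  f[1L, 1L] <- 1
  for (r in ranks2) {
    kmax <- m
    for (k in kmax:1L) {
      src <- f[k, ]
      if (any(src > 0)) {
        idx <- which(src > 0)
        f[k + 1L, idx + r] <- f[k + 1L, idx + r] + src[idx]
      }
    }
  }
  counts <- f[m + 1L, ]
  total <- sum(counts)
  sums <- 0:maxsum
  c(lower = sum(counts[sums <= w2]) / total,
    upper = sum(counts[sums >= w2]) / total)
}

#' Wilcoxon rank-sum test with an exact small-sample null
#'
#' Two-sided two-sample location test on ranks (midranks for ties). The
#' statistic is the rank sum of the first sample. For pooled sizes of at
#' most 20 the null distribution is computed exactly by convolution over
#' the observed (possibly tied) midranks; larger samples use the normal
#' approximation with tie and continuity corrections. `NaN`/`NA` values are
#' excluded per comparison, so unequal group sizes are handled naturally.
#'
#' @param x,y numeric samples.
#' @param label comparison label carried into reports (e.g. `"BM-HC"`).
#' @param exact_max_n pooled-size threshold for the exact null (default 20).
#' @return List of class `gtr_comparison` with `label`, `n_x`, `n_y`,
#'   `statistic` (rank sum of `x`), `p_value`, `method`.
#' @export
rank_sum_test <- function(x, y, label = "x-y", exact_max_n = 20L) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x) || !length(y))
    gtr_stop("empty sample after NaN exclusion", "gtr_empty_group_error")
  n_x <- length(x); n_y <- length(y); N <- n_x + n_y
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n_x)])
  if (N <= exact_max_n) {
    ranks2 <- as.integer(round(2 * r))
    tails <- rank_sum_exact_tails(ranks2, n_x, as.integer(round(2 * W)))
    p <- min(1, 2 * min(tails))
    method <- "exact"
  } else {
    mu <- n_x * (N + 1) / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n_x * n_y / 12 * ((N + 1) - tie_term)
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal_approximation"
  }
  structure(list(label = label, n_x = n_x, n_y = n_y, statistic = W,
                 p_value = p, method = method),
            class = "gtr_comparison")
}

#' @export
print.gtr_comparison <- function(x, ...) {
  cat(sprintf("%s: W = %g, n = %d vs %d, p = %.4g (%s)%s\n", x$label,
              x$statistic, x$n_x, x$n_y, x$p_value, x$method,
              if (x$p_value < 0.05) " *" else ""))
  invisible(x)
}

#' Normality screen with a transformation ladder
#'
#' Shapiro-Wilk test per group on the raw data and under each of the
#' transforms square, reciprocal, square root and natural log, each applied
#' only where its domain allows (reciprocal and log need all-positive
#' values, square root non-negative); inapplicable transforms are reported
#' as such rather than skipped silently. The screen flags whether any
#' single transform renders every group normal at p >= 0.05.
#'
#' @param groups named list of numeric vectors.
#' @param alpha normality threshold (default 0.05).
#' @return List of class `gtr_normality` with a `results` data.frame
#'   (`group, transform, applicable, W, p`) and `normal_after_any`.
#' @export
normality_screen <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  transforms <- list(
    raw = list(f = identity, ok = function(v) TRUE),
    square = list(f = function(v) v^2, ok = function(v) TRUE),
    reciprocal = list(f = function(v) 1 / v, ok = function(v) all(v > 0)),
    sqrt = list(f = sqrt, ok = function(v) all(v >= 0)),
    log = list(f = log, ok = function(v) all(v > 0)))
  rows <- list()
  for (g in names(groups)) {
    v <- groups[[g]][is.finite(groups[[g]])]
    if (length(v) < 3L)
      gtr_warn(sprintf("group '%s' has n < 3; Shapiro-Wilk skipped", g),
               "gtr_small_group_warning")
    for (tn in names(transforms)) {
      tr <- transforms[[tn]]
      row <- data.frame(group = g, transform = tn, applicable = FALSE,
                        W = NA_real_, p = NA_real_)
      if (length(v) < 3L) {
        # skipped; recorded as inapplicable
      } else if (tr$ok(v)) {
        tv <- tr$f(v)
        if (length(unique(tv)) == 1L)
          gtr_stop(sprintf("group '%s' (%s): constant sample, W undefined", g, tn),
                   "gtr_degenerate_sample_error")
        sw <- shapiro.test(tv)
        row$applicable <- TRUE
        row$W <- unname(sw$statistic); row$p <- sw$p.value
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  res <- do.call(rbind, rows)
  pass <- vapply(setdiff(names(transforms), "raw"), function(tn) {
    d <- res[res$transform == tn, ]
    nrow(d) > 0L && all(d$applicable) && all(d$p >= alpha)
  }, logical(1))
  raw_d <- res[res$transform == "raw", ]
  raw_pass <- nrow(raw_d) > 0L && all(raw_d$applicable) && all(raw_d$p >= alpha)
  structure(list(results = res, normal_after_any = any(pass) || raw_pass),
            class = "gtr_normality")
}
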