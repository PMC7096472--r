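#' Time-domain HRV descriptors
#'
#' `rmssd(rr)` is the root mean square of successive RR differences (units
#' follow the input; seconds by package convention). `pnn50(rr)` is the
#' percentage of successive differences exceeding 50 ms.
#'
#' @param rr RR intervals (s).
#' @return scalar.
#' @export
rmssd <- function(rr) {
  check_that(length(rr) >= 2L, "need at least 2 intervals")
  d <- diff(rr)
  sqrt(mean(d^2))
}

#' @rdname rmssd
#' @export
pnn50 <- function(rr) {
  check_that(length(rr) >= 2L, "need at least 2 intervals")
  d <- abs(diff(rr))
  100 * mean(d > 0.050)
}

#' Windowed averages of an instantaneous series
#'
#' Mean of the series within each `[start, end)` window; empty windows
#' yield `NA` with a flag.
#'
#' @param t time stamps (s).
#' @param x values.
#' @param windows matrix/data.frame with columns `start`, `end` (s).
#' @return data.frame with `start`, `end`, `value`, `empty`.
#' @export
window_average <- function(t, x, windows) {
  windows <- as.data.frame(windows)
  check_that(all(c("start", "end") %in% names(windows)),
             "windows needs start and end columns")
  out <- lapply(seq_len(nrow(windows)), function(i) {
    keep <- t >= windows$start[i] & t < windows$end[i] & !is.na(x)
    data.frame(start = windows$start[i], end = windows$end[i],
               value = if (any(keep)) mean(x[keep]) else NA_real_,
               empty = !any(keep))
  })
  do.call(rbind, out)
}

#' Normalize session features by each subject's neutral session
#'
#' Divides every feature of the positive/negative-session rows by the same
#' subject's neutral-session value, column by column. Zero or missing
#' neutral entries mask that column for the subject.
#'
#' @param table data.frame with `subject`, `session` columns and numeric
#'   feature columns; `session` must include a `"neutral"` row per subject.
#' @return the normalized table (neutral rows removed), with attribute
#'   `masked` counting masked cells.
#' @export
normalize_by_neutral <- function(table) {
  check_that(all(c("subject", "session") %in% names(table)),
             "table needs subject and session columns")
  feats <- setdiff(names(table), c("subject", "session", "window"))
  masked <- 0L
  parts <- lapply(split(table, table$subject), function(d) {
    neu <- d[d$session == "neutral", , drop = FALSE]
    check_that(nrow(neu) >= 1L, "subject lacks a neutral session row")
    oth <- d[d$session != "neutral", , drop = FALSE]
    for (cl in feats) {
      denom <- neu[[cl]][1]
      if (is.na(denom) || denom == 0) {
        oth[[cl]] <- NA_real_
        masked <<- masked + nrow(oth)
      } else oth[[cl]] <- oth[[cl]] / denom
    }
    oth
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  attr(out, "masked") <- masked
  out
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test with zero differences dropped (Wilcoxon's
#' rule). For n <= `exact_max` (default 12) the p-value comes from full
#' enumeration of the 2^n sign patterns (midranks for ties); otherwise a
#' normal approximation with continuity and tie corrections is used.
#'
#' @param x,y paired samples (equal length, n >= 5 before dropping zeros).
#' @param exact_max largest n for exact enumeration.
#' @return list with `statistic` (V, sum of positive ranks), `p_value`,
#'   `n_used`, `method`.
#' @export
paired_wilcoxon <- function(x, y, exact_max = 12L) {
  check_that(length(x) == length(y), "paired samples must have equal length")
  check_that(length(x) >= 5L, "need at least 5 pairs")
  d <- x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = 0, p_value = 1, n_used = 0L,
                method = "all differences zero"))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_max) {
    # enumerate all sign patterns of the ranked magnitudes
    stats_all <- vapply(0:(2^n - 1L), function(mask) {
      sum(r[bitwAnd(bitwShiftR(mask, 0:(n - 1L)), 1L) == 1L])
    }, numeric(1))
    m <- mean(stats_all)
    p <- mean(abs(stats_all - m) >= abs(v - m) - 1e-9)
    method <- "exact enumeration"
  } else {
    m <- n * (n + 1) / 4
    tie_adj <- sum(table(r)^3 - table(r)) / 48
    s <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - tie_adj)
    z <- (abs(v - m) - 0.5) / s
    p <- 2 * pnorm(-z)
    method <- "normal approximation"
  }
  list(statistic = v, p_value = min(p, 1), n_used = n, method = method)
}

#' Lilliefors-type normality check
#'
#' KS distance between the sample and a normal distribution with
#' moment-fitted mean and SD, compared against the Lilliefors critical
#' value at the 5% level (Dallal-Wilkinson approximation).
#'
#' @param x sample (n >= 5).
#' @return list with `ks`, `critical`, `normal` (logical: not rejected).
#' @export
normality_check <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  check_that(n >= 5L, "need at least 5 observations")
  if (sd(x) == 0)
    return(list(ks = Inf, critical = NA_real_, normal = FALSE,
                note = "constant sample: rejected"))
  z <- sort((x - mean(x)) / sd(x))
  p <- pnorm(z)
  emp_hi <- seq_len(n) / n
  emp_lo <- (seq_len(n) - 1) / n
  ks <- max(pmax(abs(emp_hi - p), abs(p - emp_lo)))
  crit <- 0.886 / (sqrt(n) - 0.01 + 0.85 / sqrt(n))  # alpha = 0.05
  list(ks = ks, critical = crit, normal = ks < crit)
}

#' Robust location/dispersion summary
#'
#' `median(x)` and the scaled MAD standard error
#' \eqn{1.4826\,\mathrm{MAD}(x)/\sqrt{n}} with
#' MAD = median(|x - median(x)|).
#'
#' @param x sample.
#' @return list with `median`, `dispersion`, `n`.
#' @export
robust_summary <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  check_that(n >= 1L, "empty sample")
  md <- median(x)
  madx <- median(abs(x - md))
  list(median = md, dispersion = 1.4826 * madx / sqrt(n), n = n)
}

#' Rest-vs-elicitation comparison report
#'
#' For each feature column: robust summaries per condition, a normality
#' check on the paired differences, and the paired Wilcoxon p-value.
#'
#' @param rest,elicit data.frames of per-subject feature values, rows
#'   aligned by subject.
#' @param adjust `"none"` (default; raw p-values) or `"BH"` for
#'   Benjamini-Hochberg.
#' @return data.frame with one row per feature.
#' @export
compare_conditions <- function(rest, elicit, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  feats <- intersect(names(rest), names(elicit))
  feats <- feats[vapply(feats, function(cl) is.numeric(rest[[cl]]), logical(1))]
  feats <- setdiff(feats, "subject")
  rows <- lapply(feats, function(cl) {
    xr <- rest[[cl]]; xe <- elicit[[cl]]
    keep <- !is.na(xr) & !is.na(xe)
    sr <- robust_summary(xr[keep]); se <- robust_summary(xe[keep])
    wt <- paired_wilcoxon(xr[keep], xe[keep])
    nc <- normality_check(xr[keep] - xe[keep])
    data.frame(feature = cl,
               rest_median = sr$median, rest_disp = sr$dispersion,
               elicit_median = se$median, elicit_disp = se$dispersion,
               p_value = wt$p_value, normal_diffs = nc$normal, n = sr$n)
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  out
}
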