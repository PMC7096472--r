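#' Align a point-process index series onto the EDAsymp 1 Hz clock
#'
#' Point-process series (native 5 ms-resolution trajectory) are averaged
#' within 1 s bins centred on each EDAsymp step; output is restricted to
#' the overlap of the two supports.
#'
#' @param edasymp data.frame with `t` and value column(s) on a 1 s clock.
#' @param pp data.frame with `t` and value columns on a finer clock.
#' @param bin bin width (s), default 1.
#' @return data.frame on the common clock: `t`, EDAsymp columns, binned
#'   point-process columns.
#' @export
align_series <- function(edasymp, pp, bin = 1) {
  check_that(is.data.frame(edasymp) && "t" %in% names(edasymp),
             "edasymp must be a data.frame with a t column")
  check_that(is.data.frame(pp) && "t" %in% names(pp),
             "pp must be a data.frame with a t column")
  lo <- max(min(edasymp$t), min(pp$t))
  hi <- min(max(edasymp$t), max(pp$t))
  check_that(lo <= hi, "series supports do not overlap")
  ek <- edasymp[edasymp$t >= lo - 1e-9 & edasymp$t <= hi + 1e-9, , drop = FALSE]
  check_that(nrow(ek) > 0L, "series supports do not overlap")
  vcols <- setdiff(names(pp), "t")
  binned <- lapply(ek$t, function(tc) {
    keep <- pp$t >= tc - bin / 2 & pp$t < tc + bin / 2
    if (!any(keep)) return(rep(NA_real_, length(vcols)))
    vapply(vcols, function(cl) mean(pp[[cl]][keep], na.rm = TRUE), numeric(1))
  })
  bm <- do.call(rbind, binned)
  colnames(bm) <- vcols
  out <- cbind(ek, as.data.frame(bm))
  out[complete.cases(out), , drop = FALSE]
}

#' Sympatho-vagal index: EDAsymp over a vagal denominator
#'
#' Elementwise ratio \eqn{S_X(k) = EDA_{symp}(k) / X_{pp}(k)} with
#' \eqn{X \in \{HF, LL, LH, HH\}}. Denominator samples below a floor
#' (default 1e-12 of the denominator median) are masked as missing.
#'
#' @param edasymp numeric vector.
#' @param denom numeric vector, same length.
#' @param floor_frac mask denominators below `floor_frac * median(denom)`.
#' @return numeric vector with `NA` at masked samples and attribute
#'   `fraction_masked`.
#' @export
compute_sympathovagal <- function(edasymp, denom, floor_frac = 1e-12) {
  check_that(length(edasymp) == length(denom), "series lengths differ")
  eps <- floor_frac * median(denom, na.rm = TRUE)
  bad <- is.na(denom) | denom <= max(eps, 0)
  if (all(bad)) abort("all denominator samples masked")
  s <- ifelse(bad, NA_real_, edasymp / denom)
  attr(s, "fraction_masked") <- mean(bad)
  s
}

#' Median and rectified AUC of a phasic series over a segment
#'
#' The phasic component of a wavelet decomposition is approximately
#' zero-mean, so its signed integral is uninformative; the AUC is computed
#' on the rectified series (`abs`), trapezoidally over time. Masked
#' (`NA`) samples are excluded.
#'
#' @param phasic numeric series.
#' @param t time stamps (s); default a 1 Hz clock.
#' @param segment `c(start, end)` in seconds; default full support.
#' @param rectify compute AUC on `abs(phasic)` (default TRUE).
#' @return list with `median`, `auc`, `fraction_missing`.
#' @export
phasic_quantifiers <- function(phasic, t = NULL, segment = NULL,
                               rectify = TRUE) {
  if (is.null(t)) t <- seq_along(phasic) - 1
  check_that(length(t) == length(phasic), "t and phasic lengths differ")
  if (is.null(segment)) segment <- range(t)
  keep <- t >= segment[1] & t <= segment[2]
  check_that(any(keep), "empty segment")
  x <- phasic[keep]; tk <- t[keep]
  miss <- is.na(x)
  check_that(!all(miss), "segment entirely missing")
  y <- if (rectify) abs(x) else x
  list(median = median(x, na.rm = TRUE),
       auc = trapz(tk[!miss], y[!miss]),
       fraction_missing = mean(miss))
}

#' Fuse EDA and heartbeat index series into instantaneous indices
#'
#' Builds the common 1 Hz table: EDAsymp, the binned point-process series
#' (HF, LL, LH, HH and companions), and the four sympatho-vagal ratios
#' S_HF, S_LL, S_LH, S_HH.
#'
#' @param edasymp data.frame from [compute_edasymp()].
#' @param pp_series data.frame from [pp_index_series()].
#' @return data.frame with the aligned inputs plus `s_hf`, `s_ll`, `s_lh`,
#'   `s_hh`.
#' @export
fuse_indices <- function(edasymp, pp_series) {
  al <- align_series(edasymp, pp_series)
  al$s_hf <- as.numeric(compute_sympathovagal(al$edasymp, al$hf))
  al$s_ll <- as.numeric(compute_sympathovagal(al$edasymp, al$ll))
  al$s_lh <- as.numeric(compute_sympathovagal(al$edasymp, al$lh))
  al$s_hh <- as.numeric(compute_sympathovagal(al$edasymp, al$hh))
  al
}
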