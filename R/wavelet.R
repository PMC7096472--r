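# Daubechies-5 scaling coefficients (10 taps, orthonormal, sum sqrt(2)).
DB5_H <- c(0.160102397974125, 0.603829269797473, 0.724308528438574,
           0.138428145901103, -0.242294887066190, -0.032244869585030,
           0.077571493840065, -0.006241490213012, -0.012580751999016,
           0.003335725285002)

db_filters <- function(h = DB5_H) {
  L <- length(h)
  g <- rev(h) * (-1)^(0:(L - 1L))
  list(dec_lo = rev(h), dec_hi = rev(g), rec_lo = h, rec_hi = g, L = L)
}

# One analysis step with symmetric-reflection extension. Returns slightly
# redundant coefficients (length floor((n + L - 1)/2)), which is what makes
# exact reconstruction possible under this boundary mode.
dwt_step <- function(x, flt) {
  n <- length(x); L <- flt$L
  check_that(n >= L, "series too short for the wavelet filter")
  ext <- c(rev(x[1:(L - 1L)]), x, rev(x[(n - L + 2L):n]))
  ca <- conv_fft(ext, flt$dec_lo)
  cd <- conv_fft(ext, flt$dec_hi)
  outlen <- floor((n + L - 1L) / 2L)
  idx <- seq(L + 1L, by = 2L, length.out = outlen)
  list(a = ca[idx], d = cd[idx])
}

idwt_step <- function(a, d, n, flt) {
  up <- function(v) { u <- numeric(2L * length(v)); u[seq(1L, 2L * length(v), 2L)] <- v; u }
  r <- conv_fft(up(a), flt$rec_lo) + conv_fft(up(d), flt$rec_hi)
  r[seq(flt$L - 1L, length.out = n)]
}

#' Multi-level discrete wavelet transform (db5, symmetric boundaries)
#'
#' Pyramid decomposition into approximation and detail coefficients per
#' level. Coefficient lengths are slightly redundant at the boundaries,
#' which preserves exact invertibility under symmetric-reflection
#' extension.
#'
#' @param x numeric series.
#' @param levels decomposition depth.
#' @param h scaling filter (default db5).
#' @return list of class `dwt`: `a` (level-`levels` approximation), `d`
#'   (list of details, level 1 first), `lengths` (input length per level),
#'   `levels`, `h`.
#' @export
wavelet_dwt <- function(x, levels = 5L, h = DB5_H) {
  flt <- db_filters(h)
  d <- vector("list", levels)
  lens <- integer(levels)
  a <- x
  for (lev in seq_len(levels)) {
    lens[lev] <- length(a)
    st <- dwt_step(a, flt)
    d[[lev]] <- st$d
    a <- st$a
  }
  structure(list(a = a, d = d, lengths = lens, levels = levels, h = h),
            class = "dwt")
}

#' Inverse multi-level DWT, optionally from selected coefficient groups
#'
#' Reconstructs the signal from a [wavelet_dwt()] object; `keep` selects
#' which coefficient groups survive (others are zeroed), enabling
#' band-limited reconstructions such as "level-5 details only".
#'
#' @param w a `dwt` object.
#' @param keep character vector from `c("a", "d1", ..., "d<levels>")`;
#'   default all.
#' @return numeric series of the original length.
#' @export
wavelet_idwt <- function(w, keep = NULL) {
  check_that(inherits(w, "dwt"), "w must be a dwt object")
  flt <- db_filters(w$h)
  all_names <- c("a", paste0("d", seq_len(w$levels)))
  if (is.null(keep)) keep <- all_names
  check_that(all(keep %in% all_names), "unknown coefficient group in keep")
  a <- if ("a" %in% keep) w$a else numeric(length(w$a))
  for (lev in rev(seq_len(w$levels))) {
    d <- if (paste0("d", lev) %in% keep) w$d[[lev]]
         else numeric(length(w$d[[lev]]))
    a <- idwt_step(a, d, w$lengths[lev], flt)
  }
  a
}

#' Wavelet tonic/phasic decomposition of an index series
#'
#' Five-level db5 decomposition of a 1 Hz series; the tonic (slow-trend)
#' component is reconstructed from the first-level approximation
#' coefficients (everything except the level-1 detail) and the phasic
#' (fast-oscillation) component from the level-5 detail coefficients only
#' (band about 1/64-1/32 Hz at 1 Hz sampling). Both choices are exposed:
#' `tonic_from = "a"` gives the smoother level-5 approximation instead.
#' Boundary handling is symmetric reflection; outputs match the input
#' length.
#'
#' @param x numeric series (1 Hz clock assumed).
#' @param levels decomposition depth (default 5).
#' @param tonic_from which groups form the tonic component; default the
#'   level-1 approximation, i.e. all groups except `"d1"`.
#' @param phasic_from groups forming the phasic component; default the
#'   deepest detail, `"d<levels>"`.
#' @return object of class `tonic_phasic`: `tonic`, `phasic`, `levels`.
#' @export
wavelet_tonic_phasic <- function(x, levels = 5L,
                                 tonic_from = c("a", paste0("d", setdiff(seq_len(levels), 1L))),
                                 phasic_from = paste0("d", levels)) {
  check_that(length(x) >= 2^levels * length(DB5_H),
             sprintf("series shorter than 2^%d x filter length", levels))
  check_that(!anyNA(x), "series contains NA")
  w <- wavelet_dwt(x, levels = levels)
  structure(list(tonic = wavelet_idwt(w, keep = tonic_from),
                 phasic = wavelet_idwt(w, keep = phasic_from),
                 levels = levels, tonic_from = tonic_from,
                 phasic_from = phasic_from),
            class = "tonic_phasic")
}
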