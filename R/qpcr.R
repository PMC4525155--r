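#' Representative rER of a qPCR amplicon
#'
#' The minimum rER over the unmasked bins overlapping the amplicon
#' interval is used as the representative value: qPCR measures the least
#' enriched fragment population the primers can amplify, so the minimum
#' is the conservative match to a percent-input readout.
#'
#' @param profile an [compute_rer()] profile.
#' @param chrom chromosome name.
#' @param start,end amplicon interval, 0-based half-open.
#' @param site optional site name used in error messages.
#' @return the minimum rER over unmasked overlapping bins.
#' @export
amplicon_rer <- function(profile, chrom, start, end, site = NULL) {
  track <- as_binned_track(profile)
  if (!chrom %in% names(track$values))
    stop("unknown chromosome: ", chrom)
  bs <- track$bin_size
  b1 <- floor(start / bs) + 1L
  b2 <- min(length(track$values[[chrom]]), ceiling(end / bs))
  if (b2 < b1) stop("empty amplicon interval")
  ok <- !track$mask[[chrom]][b1:b2]
  if (!any(ok))
    stop("amplicon ", if (is.null(site)) sprintf("%s:%d-%d", chrom, start, end)
         else site, " overlaps no unmasked bin")
  min(track$values[[chrom]][b1:b2][ok])
}

#' Fit the qPCR-vs-rER anchor regression
#'
#' Zero-intercept least squares of percent-input (response) on the
#' representative rER (predictor): `slope = sum(q*r) / sum(r^2)`. A pure
#' multiplicative rescaling can only align regression lines through the
#' origin, so the intercept is fixed at zero by construction. Pearson's r
#' is computed on the raw pairs; a constant percent-input column gives
#' r = 0 with a degenerate flag.
#'
#' @param anchors data frame with columns `site`, `chrom`, `start`,
#'   `end`, `percent_input`.
#' @param profile an [compute_rer()] profile.
#' @return object of class `scaling_fit`: `slope`, `pearson_r`, `n`,
#'   `degenerate`, and the per-anchor `pairs` data frame (site, rer,
#'   percent_input).
#' @export
fit_anchor_regression <- function(anchors, profile) {
  stopifnot(all(c("site", "chrom", "start", "end", "percent_input")
                %in% names(anchors)))
  r <- vapply(seq_len(nrow(anchors)), function(j)
    amplicon_rer(profile, anchors$chrom[j], anchors$start[j],
                 anchors$end[j], anchors$site[j]), numeric(1))
  q <- anchors$percent_input
  usable <- is.finite(r) & is.finite(q)
  if (sum(usable) < 3)
    stop("need at least 3 usable anchors, got ", sum(usable))
  r <- r[usable]; q <- q[usable]
  if (stats::sd(r) == 0)
    stop("all representative rER values are equal; regression undefined")
  slope <- sum(q * r) / sum(r^2)
  degenerate <- stats::sd(q) == 0
  pearson_r <- if (degenerate) 0 else stats::cor(r, q)
  structure(list(slope = slope, pearson_r = pearson_r, n = length(r),
                 degenerate = degenerate,
                 pairs = data.frame(site = anchors$site[usable], rer = r,
                                    percent_input = q)),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit> slope=%.4g %%input per rER, r=%.4f, n=%d%s\n",
              x$slope, x$pearson_r, x$n,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Rescale a profile onto a reference sample's qPCR scale
#'
#' Multiplies every rER value of the non-reference profile by
#' `c = slope_other / slope_ref`, so that the anchor regression line of
#' the rescaled profile coincides with the reference sample's line.
#' Total-read normalization cannot compare samples whose global ChIP
#' efficiency differs; the qPCR anchors supply the external standard.
#' The mean-1 property of the rescaled profile is intentionally broken
#' and the profile is flagged as externally scaled.
#'
#' @param profile_other the profile to rescale.
#' @param fit_ref,fit_other [fit_anchor_regression()] fits for the
#'   reference and the non-reference sample.
#' @return the rescaled `rer_profile` with `externally_scaled = TRUE`
#'   and `rescale_constant` set.
#' @export
rescale_profile <- function(profile_other, fit_ref, fit_other) {
  stopifnot(inherits(fit_ref, "scaling_fit"), inherits(fit_other, "scaling_fit"))
  if (fit_ref$slope <= 0 || fit_other$slope <= 0)
    stop("rescaling requires positive anchor regression slopes")
  const <- fit_other$slope / fit_ref$slope
  out <- profile_other
  out$track$values <- lapply(out$track$values, function(v) v * const)
  out$chip_rel <- profile_other$chip_rel  # intensity floor is unaffected
  out$externally_scaled <- TRUE
  out$rescale_constant <- const * profile_other$rescale_constant
  out
}

#' Validate a profile against its qPCR anchors
#'
#' Refits the anchor regression and reports per-site residuals and a
#' pass/fail decision against a correlation threshold (default 0.95, the
#' level at which a multiplicative cross-sample adjustment is considered
#' trustworthy).
#'
#' @param anchors anchor data frame (see [fit_anchor_regression()]).
#' @param profile an [compute_rer()] profile.
#' @param r_threshold minimum Pearson correlation to pass.
#' @return list with `fit`, `pass`, `r_threshold` and `residuals` (data
#'   frame site/rer/percent_input/fitted/residual).
#' @export
validate_profile <- function(anchors, profile, r_threshold = 0.95) {
  fit <- fit_anchor_regression(anchors, profile)
  res <- fit$pairs
  res$fitted <- fit$slope * res$rer
  res$residual <- res$percent_input - res$fitted
  list(fit = fit,
       pass = !fit$degenerate && fit$pearson_r >= r_threshold,
       r_threshold = r_threshold,
       residuals = res)
}
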