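#' Tumor volume from caliper diameters
#'
#' `V (mm^3) = d^2 * D / 2` with `d` the smallest and `D` the largest
#' perpendicular tumor diameter (mm).
#'
#' @param d,D diameters in mm, `0 < d <= D`. Vectorized.
#' @return volume(s) in mm^3.
#' @export
tumor_volume <- function(d, D) {
  if (any(d <= 0 | D <= 0)) stop("diameters must be positive", call. = FALSE)
  if (any(d > D))
    stop("d must be the smallest diameter (d <= D); arguments look swapped",
         call. = FALSE)
  d^2 * D / 2
}

#' Tumor growth inhibition (TGI, %)
#'
#' Defined on mean volume change from baseline:
#' `100 * (1 - mean(treated) / mean(control))`. 0% means treated grew like
#' control, 100% is stasis, values above 100% indicate net regression.
#' With `method = "endpoint"` the same formula is applied to endpoint
#' volumes instead of changes.
#'
#' @param treated,control numeric vectors: per-animal volume changes from
#'   baseline (mm^3), or endpoint volumes when `method = "endpoint"`.
#' @param method `"delta"` (default) or `"endpoint"`.
#' @return TGI in percent.
#' @export
tgi_percent <- function(treated, control, method = c("delta", "endpoint")) {
  method <- match.arg(method)
  if (length(treated) == 0L || length(control) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  mc <- mean(control)
  if (mc <= 0)
    stop("control group mean ", if (method == "delta") "change " else "",
         "must be positive; TGI is undefined under control regression",
         call. = FALSE)
  100 * (1 - mean(treated) / mc)
}

#' Per-animal tumor regression (%)
#'
#' `100 * (baseline - current) / baseline`: 100% is complete regression, 0%
#' stasis, negative values report growth. The value cannot exceed 100 for a
#' non-negative current volume. Groups are conventionally summarized by the
#' median (see [median_regression()]).
#'
#' @param baseline,current volumes in mm^3 (vectorized); `baseline > 0`,
#'   `current >= 0`.
#' @return regression percentage(s).
#' @export
regression_percent <- function(baseline, current) {
  if (any(baseline <= 0)) stop("baseline volumes must be positive",
                               call. = FALSE)
  if (any(current < 0)) stop("current volumes must be non-negative",
                             call. = FALSE)
  100 * (baseline - current) / baseline
}

#' @rdname regression_percent
#' @export
median_regression <- function(baseline, current) {
  stats::median(regression_percent(baseline, current))
}

#' Relative quantification by the comparative-Ct method
#'
#' `dCt = Ct_target - Ct_reference` per condition; `ddCt = dCt_sample -
#' dCt_calibrator`; `RQ = 2^(-ddCt)`. RQ is the target's mRNA level in the
#' sample relative to the calibrator, normalized to the reference gene.
#'
#' @param sample,calibrator numeric vectors of length 2,
#'   `c(target = Ct, reference = Ct)`; Ct values must be finite and
#'   positive.
#' @return list with `delta_ct`, `delta_delta_ct`, `rq`.
#' @export
relative_quantification <- function(sample, calibrator) {
  chk <- function(x, what) {
    x <- unlist(x)
    if (length(x) != 2L || any(!is.finite(x)) || any(x <= 0))
      stop(what, " must be two finite positive Ct values (target, reference)",
           call. = FALSE)
    x
  }
  s <- chk(sample, "sample"); k <- chk(calibrator, "calibrator")
  d_s <- s[[1L]] - s[[2L]]
  d_k <- k[[1L]] - k[[2L]]
  ddct <- d_s - d_k
  list(delta_ct = d_s, delta_delta_ct = ddct, rq = 2^(-ddct))
}
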