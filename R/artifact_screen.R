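# Epoch-level artifact screening of the raw 512 Hz signal.
#
# Each one-second epoch is summarized by two features: the peak-to-peak
# amplitude (MinMax) and the energy of the residual after subtracting a
# Savitzky-Golay smoothed version of the epoch (ESF). Blinks raise MinMax
# with little high-frequency residual, EMG raises ESF, motion raises both;
# threshold boxes in this 2-D feature space gate which seconds of the
# 1 Hz processed stream count as valid.

sg_center_coef <- function(length, order) {
  half <- (length - 1L) / 2L
  a <- outer(seq(-half, half), 0:order, `^`)
  # Center row of the least-squares projection onto degree-`order`
  # polynomials over the window.
  drop(a %*% solve(crossprod(a), t(a))[, half + 1L])
}

#' Savitzky-Golay residual of a raw epoch
#'
#' Smooths the epoch with a centered local least-squares quadratic fit
#' (order 2, window length 35) and returns the raw signal minus the
#' smoothed one. Epoch edges are handled by mirror reflection about the
#' first and last samples; on interior samples the filter reproduces any
#' polynomial of degree two or less exactly, so their residual is zero.
#'
#' @param epoch Numeric vector of raw samples.
#' @param n Required epoch length (default 512, one second at 512 Hz).
#' @param length,order Filter window length (odd) and polynomial order.
#' @return Numeric residual vector, same length as `epoch`.
#' @export
sg_residual <- function(epoch, n = 512L, length = 35L, order = 2L) {
  if (base::length(epoch) != n) {
    stop("epoch must hold exactly ", n, " samples, got ", base::length(epoch),
         call. = FALSE)
  }
  stopifnot(length %% 2 == 1, order < length)
  half <- (length - 1L) / 2L
  h <- sg_center_coef(length, order)
  padded <- c(epoch[(half + 1L):2L], epoch, epoch[(n - 1L):(n - half)])
  smoothed <- stats::filter(padded, h, sides = 2)
  epoch - as.numeric(smoothed[(half + 1L):(half + n)])
}

#' Artifact-screening features of a raw epoch
#'
#' @inheritParams sg_residual
#' @return A list with `minmax` (peak-to-peak amplitude, ADC counts) and
#'   `esf` (summed squared Savitzky-Golay residual, ADC counts squared).
#' @export
#' @examples
#' epoch_features(rep(0, 512)) # both features zero
epoch_features <- function(epoch, n = 512L) {
  res <- sg_residual(epoch, n = n)
  list(minmax = max(epoch) - min(epoch), esf = sum(res^2))
}

#' Threshold box for epoch classification
#'
#' Per-label (clean, blink) closed intervals on the two screening features.
#'
#' @param clean,blink Named lists with `minmax = c(lo, hi)` and
#'   `esf = c(lo, hi)`.
#' @return An object of class `threshold_box`.
#' @export
threshold_box <- function(clean, blink) {
  for (lab in list(clean, blink)) {
    stopifnot(all(c("minmax", "esf") %in% names(lab)))
    for (dim in c("minmax", "esf")) {
      b <- lab[[dim]]
      stop_field(base::length(b) == 2 && b[1] <= b[2], dim, "bounds need min <= max")
    }
  }
  structure(list(clean = clean, blink = blink), class = "threshold_box")
}

#' Calibrate threshold boxes from labeled epochs
#'
#' For each of the `clean` and `blink` labels, the box bounds on each
#' feature are set to the `[q, 1 - q]` empirical quantiles of that label's
#' training features. The small default trim keeps the box conservative:
#' a few extreme training epochs do not widen it.
#'
#' @param epochs List of raw epochs (numeric vectors).
#' @param labels Character vector of true labels, aligned with `epochs`;
#'   at least 10 epochs are required for each of `clean` and `blink`.
#' @param q Quantile trim per side (default 0.01).
#' @param n Epoch length.
#' @return A [threshold_box()].
#' @export
calibrate_box <- function(epochs, labels, q = 0.01, n = 512L) {
  stopifnot(base::length(epochs) == base::length(labels), q >= 0, q < 0.5)
  feats <- purrr::map(epochs, epoch_features, n = n)
  minmax <- vapply(feats, `[[`, numeric(1), "minmax")
  esf <- vapply(feats, `[[`, numeric(1), "esf")
  bounds_for <- function(lab) {
    sel <- labels == lab
    if (sum(sel) < 10) {
      stop("need >= 10 labeled '", lab, "' epochs to calibrate, got ", sum(sel),
           call. = FALSE)
    }
    list(
      minmax = unname(stats::quantile(minmax[sel], c(q, 1 - q), type = 7)),
      esf = unname(stats::quantile(esf[sel], c(q, 1 - q), type = 7))
    )
  }
  threshold_box(clean = bounds_for("clean"), blink = bounds_for("blink"))
}

inside_box <- function(features, bounds) {
  features$minmax >= bounds$minmax[1] && features$minmax <= bounds$minmax[2] &&
    features$esf >= bounds$esf[1] && features$esf <= bounds$esf[2]
}

#' Classify one epoch from its screening features
#'
#' An epoch is `clean` if its features fall inside the clean box (closed
#' intervals, so boundary values are accepted), otherwise `blink` if inside
#' the blink box, otherwise `artifact_other` (EMG and motion are not
#' distinguished at gating time).
#'
#' @param features Output of [epoch_features()].
#' @param box A calibrated [threshold_box()].
#' @return One of `"clean"`, `"blink"`, `"artifact_other"`.
#' @export
classify_epoch <- function(features, box) {
  if (!inherits(box, "threshold_box")) {
    stop("`box` must be a calibrated threshold_box", call. = FALSE)
  }
  if (inside_box(features, box$clean)) return("clean")
  if (inside_box(features, box$blink)) return("blink")
  "artifact_other"
}

#' Gate the validity of a processed stream with artifact screening
#'
#' A second is valid iff its poor-signal flag is 0 and, when raw epochs are
#' supplied, the epoch ending at that second is labeled clean. Invalid
#' seconds are flagged, never dropped, so downstream metrics can account
#' for them. Supplying epochs can only shrink the set of valid seconds.
#'
#' @param session Session tibble (one row per second).
#' @param epochs Optional list of raw epochs, one per row of `session`; if
#'   `NULL`, only poor-signal gating applies.
#' @param box A [threshold_box()]; required when `epochs` is given.
#' @param n Epoch length.
#' @return `session` with its `valid` column updated and, when epochs are
#'   screened, an `epoch_label` column.
#' @export
screen_stream <- function(session, epochs = NULL, box = NULL, n = 512L) {
  valid <- session$poor_signal == 0
  if (!is.null(epochs)) {
    if (base::length(epochs) != nrow(session)) {
      stop("epoch/stream misalignment: ", base::length(epochs), " epochs for ",
           nrow(session), " stream seconds (first unmatched index ",
           min(base::length(epochs), nrow(session)) + 1, ")", call. = FALSE)
    }
    if (is.null(box)) stop("`box` is required to screen raw epochs", call. = FALSE)
    labels <- vapply(epochs, function(e) classify_epoch(epoch_features(e, n = n), box),
                     character(1))
    session$epoch_label <- labels
    valid <- valid & labels == "clean"
  }
  session$valid <- valid
  session
}
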