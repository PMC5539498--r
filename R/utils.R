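# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed, runs `code`, and restores the caller's RNG state so
#' that package functions never disturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic small integer hash of a string, for per-subject seed
# derivation. Kept below 2^31 - 1.
hash_id <- function(id) {
  codes <- utf8ToInt(as.character(id))
  h <- 7L
  for (c in codes) h <- (h * 131L + c) %% 1009001L
  h
}

#' Power-band names used by the sensor stream
#'
#' The sensor reports its spectrum as 8 bands (delta, theta, low/high alpha,
#' low/high beta, low/mid gamma); a 9-band variant appends a high-gamma
#' band. Analyses collapse these onto the five canonical bands
#' (delta, theta, alpha, beta, gamma) by summing the split bands.
#'
#' @param n_bands Number of bands, 8 or 9.
#' @return Character vector of band names, in stream order.
#' @export
#' @examples
#' band_names(8)
band_names <- function(n_bands = 8) {
  base <- c(
    "delta", "theta", "low_alpha", "high_alpha",
    "low_beta", "high_beta", "low_gamma", "mid_gamma", "high_gamma"
  )
  if (!n_bands %in% c(8L, 9L)) {
    stop("n_bands must be 8 or 9, got ", n_bands, call. = FALSE)
  }
  base[seq_len(n_bands)]
}

band_cols <- function(n_bands) paste0("band_", seq_len(n_bands))

n_bands_of <- function(data) {
  sum(grepl("^band_[0-9]+$", names(data)))
}

# Per-second canonical band series (delta, theta, alpha, beta, gamma) from
# the band_1..band_N columns of a sample table.
canonical_band_series <- function(samples) {
  nb <- n_bands_of(samples)
  if (nb < 8) stop("expected at least 8 band columns, found ", nb, call. = FALSE)
  b <- function(i) samples[[paste0("band_", i)]]
  gamma <- b(7) + b(8)
  if (nb >= 9) gamma <- gamma + b(9)
  tibble::tibble(
    delta = b(1),
    theta = b(2),
    alpha = b(3) + b(4),
    beta = b(5) + b(6),
    gamma = gamma
  )
}

stop_field <- function(ok, field, what) {
  if (!ok) stop("invalid `", field, "`: ", what, call. = FALSE)
}
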