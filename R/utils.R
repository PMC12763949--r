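# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
vibremg_error <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "vibremg_error", "error")))
}

format_error    <- function(msg) vibremg_error(msg, "vibremg_format_error")
data_error      <- function(msg) vibremg_error(msg, "vibremg_data_error")
parameter_error <- function(msg) vibremg_error(msg, "vibremg_parameter_error")
onset_error     <- function(msg) vibremg_error(msg, "vibremg_onset_error")
threshold_error <- function(msg) vibremg_error(msg, "vibremg_threshold_error")
segmentation_error <- function(msg) vibremg_error(msg, "vibremg_segmentation_error")
selection_error <- function(msg) vibremg_error(msg, "vibremg_selection_error")
metric_error    <- function(msg) vibremg_error(msg, "vibremg_metric_error")
ratio_error     <- function(msg) vibremg_error(msg, "vibremg_ratio_error")
manifest_error  <- function(msg) vibremg_error(msg, "vibremg_manifest_error")
fit_error       <- function(msg) vibremg_error(msg, "vibremg_fit_error")
test_error      <- function(msg) vibremg_error(msg, "vibremg_test_error")

# Centered moving average with edge shrinkage (window truncated at the ends).
# O(n) via cumulative sums; effective window is 2*floor(width/2) + 1 samples.
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  half <- width %/% 2L
  if (half == 0L) return(x)
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Locate peaks by prominence and minimum separation
#'
#' Strict local maxima are ranked by height and greedily retained subject to a
#' minimum inter-peak distance; peaks whose topographic prominence falls below
#' `min_prominence` are discarded. Plateaus count once (first sample).
#'
#' @param x numeric signal.
#' @param min_distance minimum separation between retained peaks, in samples.
#' @param min_prominence minimum prominence (same units as `x`).
#' @return integer vector of peak indices, ascending.
#' @noRd
find_peaks <- function(x, min_distance = 1L, min_prominence = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  # local maxima via sign-run analysis (plateau-safe: first plateau sample)
  s <- sign(diff(x))
  r <- rle(s)
  k <- length(r$values)
  ends <- cumsum(r$lengths)           # run ends, in diff coordinates
  idx <- seq_len(k)
  last_nz <- cummax(ifelse(r$values != 0, idx, 0L))
  prev_nz <- c(0L, last_nz[-k])       # last nonzero run strictly before run j
  is_fall <- r$values == -1 & prev_nz > 0
  cand <- ends[prev_nz[which(is_fall & r$values[pmax(prev_nz, 1L)] == 1)]] + 1L
  cand <- sort(unique(cand))
  if (!length(cand)) return(integer(0))

  # topographic prominence from the peak/valley skeleton: precompute the
  # minimum of x on each inter-peak segment (plus the two edge segments)
  bounds <- c(1L, cand, n)
  segmin <- vapply(seq_len(length(bounds) - 1L), function(i) {
    min(x[bounds[i]:bounds[i + 1L]])
  }, numeric(1))                      # segmin[i]: between cand[i-1] and cand[i]
  m <- length(cand)
  heights <- x[cand]
  prom <- numeric(m)
  for (i in seq_len(m)) {
    h <- heights[i]
    lmin <- segmin[i]                 # segment immediately left of peak i
    j <- i - 1L
    while (j >= 1L && heights[j] <= h) {
      lmin <- min(lmin, segmin[j])
      j <- j - 1L
    }
    rmin <- segmin[i + 1L]
    j <- i + 1L
    while (j <= m && heights[j] <= h) {
      rmin <- min(rmin, segmin[j + 1L])
      j <- j + 1L
    }
    prom[i] <- h - max(lmin, rmin)
  }
  cand <- cand[prom >= min_prominence]
  if (!length(cand)) return(integer(0))

  # enforce min distance, keeping taller peaks first
  ord <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (p in ord) {
    if (!length(kept) || all(abs(kept - p) >= min_distance)) kept <- c(kept, p)
  }
  sort(kept)
}

# Run the body with a deterministic RNG state, restoring the caller's state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}
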