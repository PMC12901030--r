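#' Attentional vector from the three channel responses
#'
#' Reconstructs the momentary focus of covert spatial attention as the planar
#' vector sum of the three unit directions at 0, 120 and 240 degrees (top,
#' left, right; 0 = vertical up, counter-clockwise positive), each scaled by
#' the signed channel response. The vector length indexes attention strength;
#' its angle the attention locus; the maximum angular similarity (MAS) the
#' selectivity for one alternative. Negative channel responses are used as-is
#' unless `rectify = TRUE`.
#'
#' @param channel_response A `channel_response` from [invert_model()]
#'   (`response` array `[trials x 3 x time]`), or a plain `[3 x time]` matrix.
#' @param rectify Half-wave rectify the channel responses before summation.
#' @param length_tol Vector lengths below this are treated as zero and their
#'   angle (and MAS) flagged `NA`.
#' @return A list of class `attention_trace` with matrices `[trials x time]`:
#'   `length` (strength), `angle` (degrees in the 0-up CCW convention, `NA`
#'   where undefined), `mas`, plus `fs`, `t0` and `centers`.
#' @export
attentional_vector <- function(channel_response, rectify = FALSE,
                               length_tol = 1e-12) {
  if (is.matrix(channel_response)) {
    resp <- array(channel_response,
                  c(1, nrow(channel_response), ncol(channel_response)))
    fs <- 1; t0 <- 0
    centers <- c(0, 120, 240)
  } else {
    resp <- channel_response$response
    fs <- channel_response$fs %||% 1
    t0 <- channel_response$t0 %||% 0
    centers <- channel_response$centers %||% c(0, 120, 240)
  }
  if (dim(resp)[2] != 3L)
    stop("the attentional vector is defined for exactly 3 channels")
  if (rectify) resp <- pmax(resp, 0)
  # direction of angle theta (0 deg up, CCW positive): (cos, sin)(theta + 90)
  ux <- cos(deg2rad(centers + 90))
  uy <- sin(deg2rad(centers + 90))
  d <- dim(resp)
  vx <- matrix(0, d[1], d[3]); vy <- matrix(0, d[1], d[3])
  for (k in 1:3) {
    vx <- vx + resp[, k, ] * ux[k]
    vy <- vy + resp[, k, ] * uy[k]
  }
  len <- sqrt(vx^2 + vy^2)
  ang <- (atan2(vy, vx) * 180 / pi - 90) %% 360
  ang[len < length_tol] <- NA_real_
  structure(list(length = len, angle = ang,
                 mas = max_angular_similarity(ang, centers),
                 fs = fs, t0 = t0, centers = centers),
            class = "attention_trace")
}

#' Maximum angular similarity (MAS)
#'
#' The largest cosine between the attentional-vector angle and the target
#' angles. With three equally spaced targets the minimum over angles is 0.5,
#' attained exactly midway between two targets; MAS = 1 means the vector
#' points straight at one alternative.
#'
#' @param angle Angle(s) in degrees (vector, matrix or array); `NA` (undefined
#'   angle at zero vector length) propagates.
#' @param centers Target angles in degrees.
#' @return MAS with the same shape as `angle`.
#' @export
#' @examples
#' max_angular_similarity(0)    # 1
#' max_angular_similarity(60)   # 0.5
max_angular_similarity <- function(angle, centers = c(0, 120, 240)) {
  out <- rep(-Inf, length(angle))
  for (mu in centers) out <- pmax(out, cos(deg2rad(angle - mu)))
  out[is.na(angle)] <- NA_real_
  attributes(out) <- attributes(angle)
  out
}

#' Nearest target (attention locus) of an angle
#'
#' @param angle Angle(s) in degrees.
#' @param centers Target angles in degrees.
#' @param prefer Optional locus given priority at exact similarity ties
#'   (conservative against spurious switches).
#' @return The target angle(s) with the highest angular similarity.
#' @export
nearest_target <- function(angle, centers = c(0, 120, 240), prefer = NULL) {
  sim <- vapply(centers, function(mu) cos(deg2rad(angle - mu)),
                numeric(length(angle)))
  sim <- matrix(sim, ncol = length(centers))
  best <- max.col(sim, ties.method = "first")
  if (!is.null(prefer)) {
    pk <- match(prefer, centers)
    tie <- !is.na(pk) & abs(sim[cbind(seq_along(best), pk)] -
                              sim[cbind(seq_along(best), best)]) < 1e-12
    best[tie] <- pk[tie]
  }
  out <- centers[best]
  out[is.na(angle)] <- NA_real_
  out
}

#' Z-score attention strength over the stimulus-on period
#'
#' Normalizes the strength trace using the mean and standard deviation pooled
#' over all trials' samples inside `window`, applied to the whole trace (one
#' normalization per participant/session).
#'
#' @param trace An `attention_trace`.
#' @param window Two seconds `(from, to)` on the epoch time axis defining the
#'   normalization (stimulus-on) samples.
#' @return The trace with `length` replaced by its z-scored version and the
#'   normalization constants in `norm`.
#' @export
zscore_strength <- function(trace, window) {
  tt <- epoch_times(trace)
  idx <- which(tt >= window[1] - 1e-9 & tt <= window[2] + 1e-9)
  if (length(idx) == 0L) stop("normalization window outside the trace")
  vals <- trace$length[, idx]
  m <- mean(vals, na.rm = TRUE)
  s <- stats::sd(vals, na.rm = TRUE)
  if (!is.finite(s) || s < 1e-15)
    stop("zero variance in the normalization window")
  trace$length <- (trace$length - m) / s
  trace$norm <- c(mean = m, sd = s)
  trace
}
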