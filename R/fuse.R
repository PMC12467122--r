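#' Kalman state for the HR fusion filter
#'
#' Linear-Gaussian state-space model `x_k = A x_{k-1} + w`,
#' `f_i(k) = H x_k + v_i(k)` for the two per-chunk measurements
#' `f0` (coarse) and `f1` (fine) of the same HR state. The default is a
#' scalar random walk (`A = H = 1`) in bpm, but all matrices may be given
#' in general form.
#'
#' The default noise variances weight the fine stage as the more reliable
#' measurement (`R1 < R0`), matching the observed ordering of the
#' per-stage errors; they are surrogates tuned on the simulator, not
#' physical constants, and are fully configurable.
#'
#' @param x0 initial state (bpm for the scalar model).
#' @param P0 initial covariance.
#' @param A system matrix.
#' @param H measurement matrix (row vector for scalar measurements).
#' @param Q process-noise covariance (bpm^2 per chunk).
#' @param R0,R1 measurement-noise variances of `f0` and `f1` (bpm^2).
#' @return an object of class `kalman_state`.
#' @export
kalman_state <- function(x0 = 70, P0 = 100, A = 1, H = 1, Q = 0.5,
                         R0 = 25, R1 = 9) {
  stopifnot(R0 > 0, R1 > 0)
  A <- as.matrix(A); H <- matrix(H, nrow = 1)
  structure(list(x = matrix(x0, ncol = 1), P = as.matrix(P0), A = A, H = H,
                 Q = as.matrix(Q), R0 = R0, R1 = R1, k = 0L),
            class = "kalman_state")
}

#' Kalman prediction step
#'
#' `x_k|k-1 = A x_k-1|k-1`, `P_k|k-1 = A P A' + Q`.
#'
#' @param state a [kalman_state()].
#' @return the predicted state.
#' @export
kf_predict <- function(state) {
  stopifnot(inherits(state, "kalman_state"))
  state$x <- state$A %*% state$x
  state$P <- state$A %*% state$P %*% t(state$A) + state$Q
  state$P <- (state$P + t(state$P)) / 2
  state
}

## One scalar measurement update with noise variance R.
kf_update <- function(state, z, R) {
  H <- state$H
  S <- drop(H %*% state$P %*% t(H)) + R
  K <- state$P %*% t(H) / S
  state$x <- state$x + K %*% (z - H %*% state$x)
  P <- (diag(nrow(state$P)) - K %*% H) %*% state$P
  state$P <- (P + t(P)) / 2
  state
}

#' Sequential measurement update with the chunk pair (f0, f1)
#'
#' Applies the two scalar updates in order: first the coarse measurement
#' `f0` with gain `K0 = P H' / (H P H' + R0)`, then, starting from that
#' intermediate posterior, the fine measurement `f1` with `R1`. Processing
#' the stacked 2-vector measurement in one batch update gives the identical
#' posterior; the sequential form simply avoids the 2x2 inversion.
#'
#' A missing or invalid `f0` skips the first update; a fallback-flagged
#' `f1` is applied with `R1 * r1_inflation`. If both measurements are
#' missing the prediction is returned unchanged with
#' `attr(, "no_measurement") = TRUE`.
#'
#' @param state the predicted [kalman_state()].
#' @param f0,f1 measurements (bpm); `NA` = missing.
#' @param f0_valid logical; `FALSE` skips the `f0` update.
#' @param f1_fallback logical; `TRUE` inflates `R1`.
#' @param r1_inflation inflation factor for fallback chunks.
#' @return the a-posteriori state.
#' @export
sequential_update <- function(state, f0, f1, f0_valid = TRUE,
                              f1_fallback = FALSE, r1_inflation = 4) {
  stopifnot(inherits(state, "kalman_state"))
  used <- FALSE
  if (!is.na(f0) && isTRUE(f0_valid)) {
    state <- kf_update(state, f0, state$R0)
    used <- TRUE
  }
  if (!is.na(f1)) {
    R1 <- state$R1 * if (isTRUE(f1_fallback)) r1_inflation else 1
    state <- kf_update(state, f1, R1)
    used <- TRUE
  }
  if (!used) attr(state, "no_measurement") <- TRUE
  state$k <- state$k + 1L
  state
}

#' Run the sequential Kalman filter over all chunks
#'
#' Fuses the per-chunk coarse/fine pairs into one HR trace: for every
#' chunk a prediction step is followed by the two sequential updates. The
#' state is initialized at the first available valid `f0` (else `f1`)
#' with covariance `P0`.
#'
#' @param pairs `data.frame` with columns `f0_bpm`, `f1_bpm`, and
#'   optionally `f0_valid` and `f1_fallback`.
#' @param Q,R0,R1,P0 filter parameters (see [kalman_state()]).
#' @param r1_inflation `R1` inflation for fallback chunks.
#' @return `data.frame(chunk_index, hr_skf_bpm, P, no_measurement)` with
#'   one a-posteriori estimate per chunk (0-based chunk indices).
#' @export
run_skf <- function(pairs, Q = 0.5, R0 = 25, R1 = 9, P0 = 100,
                    r1_inflation = 4) {
  n <- nrow(pairs)
  stopifnot(n >= 1)
  f0 <- pairs$f0_bpm
  f1 <- pairs$f1_bpm
  f0_valid <- if ("f0_valid" %in% names(pairs)) pairs$f0_valid else !is.na(f0)
  f1_fb <- if ("f1_fallback" %in% names(pairs)) pairs$f1_fallback else rep(FALSE, n)
  cand0 <- which(!is.na(f0) & f0_valid)
  x0 <- if (length(cand0)) f0[cand0[1]] else {
    cand1 <- which(!is.na(f1))
    if (!length(cand1)) stop("no usable measurement in any chunk")
    f1[cand1[1]]
  }
  state <- kalman_state(x0 = x0, P0 = P0, Q = Q, R0 = R0, R1 = R1)
  hr <- numeric(n)
  Pv <- numeric(n)
  nomeas <- logical(n)
  for (k in seq_len(n)) {
    state <- kf_predict(state)
    state <- sequential_update(state, f0[k], f1[k], f0_valid[k], f1_fb[k],
                               r1_inflation)
    hr[k] <- drop(state$x)[1]
    Pv[k] <- state$P[1, 1]
    nomeas[k] <- isTRUE(attr(state, "no_measurement"))
    attr(state, "no_measurement") <- NULL
  }
  data.frame(chunk_index = seq_len(n) - 1L, hr_skf_bpm = hr, P = Pv,
             no_measurement = nomeas)
}
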