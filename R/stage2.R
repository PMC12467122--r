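#' Sine/cosine frequency basis for the line-spectrum problem
#'
#' Builds the dictionary `Phi` over one chunk: column `m` (1..M) is
#' `sin(2 pi f_m t_n)` and column `M+m` is `cos(2 pi f_m t_n)`, for a
#' frequency grid of `M` points spanning `f_lo`..`f_hi` inclusive. With
#' the defaults (100 samples at 20 Hz, M = 200 over 0.5--2.5 Hz) the basis
#' is a 100 x 400 matrix, heavily overcomplete: the sparse Bayesian fit is
#' what makes the inverse problem well-posed.
#'
#' @param n_chunk chunk length `N` in samples.
#' @param fs sampling rate (Hz).
#' @param f_lo,f_hi frequency grid limits (Hz), both inclusive.
#' @param M number of grid frequencies.
#' @return an object of class `frequency_basis`: `t` (s, length `N`),
#'   `f` (Hz, length `M`), `Phi` (`N x 2M`).
#' @export
#' @examples
#' bb <- build_basis()
#' dim(bb$Phi)   # 100 x 400
build_basis <- function(n_chunk = 100, fs = 20, f_lo = 0.5, f_hi = 2.5,
                        M = 200) {
  stopifnot(n_chunk >= 2, M >= 2, f_lo > 0, f_hi > f_lo)
  if (f_hi > fs / 2) stop("f_hi = ", f_hi, " Hz exceeds Nyquist fs/2")
  t <- (seq_len(n_chunk) - 1) / fs
  f <- seq(f_lo, f_hi, length.out = M)
  ang <- 2 * pi * outer(t, f)
  structure(list(t = t, f = f, Phi = cbind(sin(ang), cos(ang))),
            class = "frequency_basis")
}

#' Default Stage 2 / RVM configuration
#'
#' @param max_iter maximum ARD iterations.
#' @param tol convergence tolerance on the largest change of `log(alpha)`.
#' @param prune_alpha precision above which a weight is pruned to zero.
#' @param sigma2_floor lower bound of the noise-variance re-estimate.
#' @param half_width_bpm half width of the fine search window around the
#'   coarse estimate; 12.5 bpm = 0.208 Hz.
#' @param min_prominence_frac prominence threshold for window peaks, as a
#'   fraction of the window maximum.
#' @param r1_inflation factor by which the fusion stage inflates the Stage
#'   2 measurement-noise variance when the window fallback was used.
#' @return named list of settings.
#' @export
stage2_config <- function(max_iter = 500, tol = 1e-6, prune_alpha = 1e9,
                          sigma2_floor = 1e-12, half_width_bpm = 12.5,
                          min_prominence_frac = 0.05, r1_inflation = 4) {
  list(max_iter = max_iter, tol = tol, prune_alpha = prune_alpha,
       sigma2_floor = sigma2_floor, half_width_bpm = half_width_bpm,
       min_prominence_frac = min_prominence_frac,
       r1_inflation = r1_inflation)
}

#' Sparse Bayesian (relevance vector) fit of a chunk
#'
#' Solves `y = Phi x + eps` for a sparse weight vector by automatic
#' relevance determination: every weight carries its own prior precision
#' `alpha_m`, the precisions are re-estimated by evidence maximization
#' (`alpha_m <- gamma_m / mu_m^2` with `gamma_m = 1 - alpha_m Sigma_mm`),
#' and weights whose precision diverges are pruned exactly to zero. The
#' noise variance is re-estimated each iteration from the residual. The
#' posterior moments are computed through the N x N form of the Woodbury
#' identity, so the cost is governed by the chunk length (100), not the
#' dictionary size (400). The procedure has no random initialization:
#' repeated calls are bit-identical.
#'
#' @param basis a [build_basis()] result.
#' @param y chunk samples; `length(y)` must equal `nrow(basis$Phi)`.
#' @param config a [stage2_config()].
#' @return an object of class `rvm_fit`: `mu` (posterior means, length
#'   `2M`, pruned weights exactly zero), `alpha`, `noise_var`,
#'   `n_relevant`, `converged`, `n_iter`.
#' @export
rvm_fit <- function(basis, y, config = stage2_config()) {
  stopifnot(inherits(basis, "frequency_basis"))
  Phi <- basis$Phi
  N <- nrow(Phi)
  M2 <- ncol(Phi)
  if (length(y) != N) stop("length(y) = ", length(y), " != N = ", N)
  if (!all(is.finite(y))) stop("y contains non-finite values")
  alpha <- rep(1e-6, M2)
  active <- seq_len(M2)
  sigma2 <- max(0.1 * stats::var(y), config$sigma2_floor)
  mu_full <- numeric(M2)
  converged <- FALSE
  it <- 0L
  while (it < config$max_iter && length(active)) {
    it <- it + 1L
    Pa <- Phi[, active, drop = FALSE]
    Ainv <- 1 / alpha[active]
    C <- sigma2 * diag(N) + Pa %*% (Ainv * t(Pa))
    R <- tryCatch(chol(C), error = function(e)
      chol(C + 1e-10 * mean(diag(C)) * diag(N)))
    Ci_y <- backsolve(R, forwardsolve(t(R), y))
    Ci_P <- backsolve(R, forwardsolve(t(R), Pa))
    mu <- Ainv * drop(crossprod(Pa, Ci_y))
    Sii <- pmax(Ainv - Ainv^2 * colSums(Pa * Ci_P), 0)
    gam <- pmin(pmax(1 - alpha[active] * Sii, 1e-12), 1)
    old_alpha <- alpha[active]
    new_alpha <- ifelse(mu^2 > 1e-300, gam / mu^2, Inf)
    resid <- y - drop(Pa %*% mu)
    sigma2 <- max(sum(resid^2) / max(N - sum(gam), 1e-6),
                  config$sigma2_floor)
    alpha[active] <- new_alpha
    keep <- new_alpha < config$prune_alpha
    mu_full[] <- 0
    mu_full[active[keep]] <- mu[keep]
    dal <- abs(log(pmin(new_alpha[keep], 1e300)) -
               log(pmin(old_alpha[keep], 1e300)))
    active <- active[keep]
    if (length(dal) && max(dal) < config$tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(mu = mu_full, alpha = alpha, noise_var = sigma2,
                 n_relevant = length(active), converged = converged,
                 n_iter = it),
            class = "rvm_fit")
}

#' Energy spectrum from the RVM weights
#'
#' For every grid frequency the energy is the squared modulus of its
#' sine/cosine weight pair: `P(f_m) = mu_m^2 + mu_(m+M)^2`.
#'
#' @param fit an [rvm_fit()] result (or any list with a `mu` of length
#'   `2M`).
#' @param basis the [build_basis()] used for the fit (provides the grid).
#' @return an object of class `energy_spectrum`: `f` (Hz) and `energy`
#'   (non-negative, length `M`).
#' @export
energy_spectrum <- function(fit, basis) {
  M <- length(basis$f)
  if (length(fit$mu) != 2 * M)
    stop("length(mu) = ", length(fit$mu), " != 2M = ", 2 * M)
  structure(list(f = basis$f,
                 energy = fit$mu[seq_len(M)]^2 + fit$mu[M + seq_len(M)]^2),
            class = "energy_spectrum")
}

#' Fine HR selection inside the search window
#'
#' Restricts the energy spectrum to `center +/- half_width` (default
#' 12.5 bpm = 0.208 Hz around the Stage 1 estimate), detects the local
#' maxima there, and returns the mean of the two highest peaks (one peak:
#' that peak). If no peak exists in the window, the fallback keeps
#' `f1 = center` and flags the chunk so the fusion stage down-weights it.
#'
#' @param spec an [energy_spectrum()].
#' @param center window centre (Hz), normally the coarse estimate `f0`.
#' @param half_width_bpm half window width in bpm.
#' @param min_prominence_frac prominence threshold relative to the window
#'   maximum.
#' @return an object of class `fine_estimate`: `f1` (Hz),
#'   `n_window_peaks`, `fallback_used`.
#' @export
windowed_peak_select <- function(spec, center, half_width_bpm = 12.5,
                                 min_prominence_frac = 0.05) {
  stopifnot(inherits(spec, "energy_spectrum"), is.finite(center))
  hw <- bpm_to_hz(half_width_bpm)
  lo <- center - hw
  hi <- center + hw
  inside <- which(spec$f >= lo & spec$f <= hi)
  if (!length(inside))
    stop("search window [", lo, ", ", hi, "] Hz does not intersect the grid")
  pk <- find_local_peaks(spec$energy)
  pk <- pk[pk$index %in% inside, , drop = FALSE]
  wmax <- max(spec$energy[inside])
  if (wmax > 0)
    pk <- pk[pk$prominence >= min_prominence_frac * wmax, , drop = FALSE]
  n_pk <- nrow(pk)
  if (n_pk == 0) {
    f1 <- center
    fallback <- TRUE
  } else {
    top <- pk[order(pk$value, decreasing = TRUE)[seq_len(min(2, n_pk))], ]
    f1 <- mean(spec$f[top$index])
    fallback <- FALSE
  }
  structure(list(f1 = f1, n_window_peaks = as.integer(n_pk),
                 fallback_used = fallback),
            class = "fine_estimate")
}

#' Stage 2: fine HR estimation on one chunk
#'
#' Fits the sparse line spectrum to the phase-difference chunk and selects
#' the fine estimate `f1` in a window around `center`. When the coarse
#' stage was invalid, `center` should be the previous fused estimate; when
#' no centre is available at all (`center = NA`, e.g. the first chunk),
#' the whole 0.5--2.5 Hz grid is searched and `f1` is the mean of the two
#' globally strongest peaks.
#'
#' @param chunk phase-difference samples (length `nrow(basis$Phi)`).
#' @param basis a [build_basis()].
#' @param center window centre (Hz) or `NA` for a full-band search.
#' @param config a [stage2_config()].
#' @return a `fine_estimate` with the `energy_spectrum` attached as
#'   `attr(, "spectrum")` and the fit as `attr(, "fit")`.
#' @export
stage2_estimate <- function(chunk, basis, center = NA,
                            config = stage2_config()) {
  fit <- rvm_fit(basis, chunk, config)
  spec <- energy_spectrum(fit, basis)
  if (is.na(center)) {
    mid <- mean(range(basis$f))
    est <- windowed_peak_select(spec, mid,
                                half_width_bpm = hz_to_bpm(diff(range(basis$f)) / 2),
                                min_prominence_frac = config$min_prominence_frac)
  } else {
    est <- windowed_peak_select(spec, center,
                                half_width_bpm = config$half_width_bpm,
                                min_prominence_frac = config$min_prominence_frac)
  }
  attr(est, "spectrum") <- spec
  attr(est, "fit") <- fit
  est
}
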