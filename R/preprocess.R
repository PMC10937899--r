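# The micrograph enhancement chain applied before detection:
# Gaussian -> standardization -> 8-bit grayscale -> non-local means ->
# adaptive Wiener -> CLAHE -> guided filter (CLAHE image as guide),
# each stage individually skippable. Gaussian smoothing and CLAHE come
# from EBImage; non-local means, the adaptive Wiener filter and the
# guided filter are implemented here (vectorized, integral-image based).

#' Denoising-chain configuration
#'
#' @param gaussian_sigma Gaussian pre-filter sigma in pixels.
#' @param nlmeans_strength Non-local-means filtering strength `h` on the
#'   8-bit intensity scale.
#' @param nlmeans_template_window Odd patch size for patch comparison.
#' @param nlmeans_search_window Odd search-window size.
#' @param wiener_window Odd window of the locally adaptive Wiener filter.
#' @param clahe_clip_limit CLAHE contrast clip limit.
#' @param clahe_tile_grid `c(rows, cols)` CLAHE tile grid.
#' @param guided_radius Guided-filter box radius in pixels.
#' @param guided_epsilon Guided-filter regularization (on the [0,1] scale).
#' @param gaussian,normalize,grayscale,nlmeans,wiener,clahe,guided Per-stage
#'   toggles; disabling every stage makes [denoise()] the identity.
#' @return A `denoise_config` list.
#' @export
denoise_config <- function(gaussian_sigma = 1, nlmeans_strength = 10,
                           nlmeans_template_window = 7,
                           nlmeans_search_window = 21, wiener_window = 5,
                           clahe_clip_limit = 2, clahe_tile_grid = c(8, 8),
                           guided_radius = 8, guided_epsilon = 0.01,
                           gaussian = TRUE, normalize = TRUE,
                           grayscale = TRUE, nlmeans = TRUE, wiener = TRUE,
                           clahe = TRUE, guided = TRUE) {
  odd <- function(x) x >= 1 && x %% 2 == 1
  stopifnot(gaussian_sigma > 0, nlmeans_strength > 0,
            odd(nlmeans_template_window), odd(nlmeans_search_window),
            nlmeans_search_window >= nlmeans_template_window,
            odd(wiener_window), clahe_clip_limit > 0,
            length(clahe_tile_grid) == 2, all(clahe_tile_grid >= 1),
            guided_radius >= 1)
  structure(list(gaussian_sigma = gaussian_sigma,
                 nlmeans_strength = nlmeans_strength,
                 nlmeans_template_window = as.integer(nlmeans_template_window),
                 nlmeans_search_window = as.integer(nlmeans_search_window),
                 wiener_window = as.integer(wiener_window),
                 clahe_clip_limit = clahe_clip_limit,
                 clahe_tile_grid = as.integer(clahe_tile_grid),
                 guided_radius = as.integer(guided_radius),
                 guided_epsilon = guided_epsilon,
                 stages = c(gaussian = gaussian, normalize = normalize,
                            grayscale = grayscale, nlmeans = nlmeans,
                            wiener = wiener, clahe = clahe, guided = guided)),
            class = "denoise_config")
}

#' Standardize a micrograph to zero mean and unit variance
#'
#' A constant image is mean-centered only (no division by zero), giving an
#' all-zero result.
#'
#' @param micrograph A [cryo_micrograph()] or matrix.
#' @return Same type as the input.
#' @export
normalize_standard <- function(micrograph) {
  m <- if (inherits(micrograph, "cryo_micrograph")) micrograph$pixels else micrograph
  s <- stats::sd(m)
  out <- if (s > 0) (m - mean(m)) / s else m - mean(m)
  if (inherits(micrograph, "cryo_micrograph")) {
    micrograph$pixels <- out
    micrograph
  } else out
}

#' Linear rescale to the 8-bit grayscale range
#'
#' Maps the minimum to 0 and the maximum to 255 (rounded); a constant image
#' maps to all zeros. The mapping is monotone, so pixel ordering is
#' preserved.
#'
#' @param micrograph A [cryo_micrograph()] or matrix.
#' @return Matrix of integers in `[0, 255]` (same shape).
#' @export
to_grayscale_uint <- function(micrograph) {
  m <- if (inherits(micrograph, "cryo_micrograph")) micrograph$pixels else micrograph
  stopifnot(all(is.finite(m)))
  rng <- range(m)
  if (diff(rng) == 0) return(matrix(0, nrow(m), ncol(m)))
  round((m - rng[1]) / diff(rng) * 255)
}

# mean filter over a (2r+1)^2 window with replicate padding, via summed-area
# tables; the workhorse behind NL-means, Wiener and the guided filter
box_mean <- function(m, r) {
  H <- nrow(m); W <- ncol(m)
  p <- m[c(rep(1, r), seq_len(H), rep(H, r)), c(rep(1, r), seq_len(W), rep(W, r))]
  S <- apply(apply(p, 2, cumsum), 1, cumsum)  # transposed integral image
  S <- rbind(0, cbind(0, S))                  # (W+2r+1) x (H+2r+1)
  k <- 2 * r + 1
  i1 <- seq_len(H); j1 <- seq_len(W)
  t(S[j1 + k, i1 + k, drop = FALSE] - S[j1, i1 + k, drop = FALSE] -
      S[j1 + k, i1, drop = FALSE] + S[j1, i1, drop = FALSE]) / (k * k)
}

shift_pad <- function(m, dy, dx) {
  H <- nrow(m); W <- ncol(m)
  ri <- pmin(pmax(seq_len(H) + dy, 1), H)
  ci <- pmin(pmax(seq_len(W) + dx, 1), W)
  m[ri, ci, drop = FALSE]
}

#' Non-local means denoising
#'
#' Classic NL-means: each pixel is replaced by a weighted average of pixels
#' with similar surrounding patches inside a search window, with weights
#' `exp(-patch_mse / h^2)`. Implemented by looping over search offsets and
#' box-filtering squared differences, which keeps it fully vectorized.
#'
#' @param m Matrix (8-bit scale by convention).
#' @param h Filtering strength.
#' @param template Odd patch window size.
#' @param search Odd search window size.
#' @return Denoised matrix.
#' @export
nl_means <- function(m, h = 10, template = 7, search = 21) {
  tr <- (template - 1) %/% 2
  sr <- (search - 1) %/% 2
  acc <- m          # offset (0,0): weight exp(0) = 1
  wacc <- matrix(1, nrow(m), ncol(m))
  for (dy in -sr:sr) {
    for (dx in -sr:sr) {
      if (dy == 0 && dx == 0) next
      sh <- shift_pad(m, dy, dx)
      d2 <- box_mean((m - sh)^2, tr)
      w <- exp(-d2 / (h * h))
      acc <- acc + w * sh
      wacc <- wacc + w
    }
  }
  acc / wacc
}

#' Locally adaptive Wiener filter
#'
#' Pixel-wise Wiener shrinkage toward the local mean using local variance
#' estimates in a square window; the noise power is estimated as the mean
#' of the local variances.
#'
#' @param m Matrix.
#' @param window Odd window size.
#' @return Filtered matrix.
#' @export
wiener_adaptive <- function(m, window = 5) {
  r <- (window - 1) %/% 2
  mu <- box_mean(m, r)
  vr <- pmax(box_mean(m * m, r) - mu^2, 0)
  nv <- mean(vr)
  gain <- ifelse(vr > nv, (vr - nv) / pmax(vr, .Machine$double.eps), 0)
  mu + gain * (m - mu)
}

#' Guided filter
#'
#' Edge-preserving smoothing of `m` steered by a guide image: within each
#' box window the output is an affine function of the guide, with
#' `epsilon` controlling how strongly weak guide structure is smoothed.
#'
#' @param m Input matrix (the image to be filtered).
#' @param guide Guide matrix (same size); defaults to `m`.
#' @param radius Box radius in pixels.
#' @param epsilon Regularization on the guide variance.
#' @return Filtered matrix.
#' @export
guided_filter <- function(m, guide = m, radius = 8, epsilon = 0.01) {
  stopifnot(all(dim(m) == dim(guide)))
  mean_I <- box_mean(guide, radius)
  mean_p <- box_mean(m, radius)
  cov_Ip <- box_mean(guide * m, radius) - mean_I * mean_p
  var_I <- pmax(box_mean(guide * guide, radius) - mean_I^2, 0)
  a <- cov_Ip / (var_I + epsilon)
  b <- mean_p - a * mean_I
  box_mean(a, radius) * guide + box_mean(b, radius)
}

clahe_stage <- function(m01, config) {
  if (diff(range(m01)) == 0) return(m01)  # histogram undefined on constants
  # EBImage images are x-major; transpose so tile grid rows/cols line up
  out <- EBImage::clahe(t(m01), nx = config$clahe_tile_grid[2],
                        ny = config$clahe_tile_grid[1], bins = 256,
                        limit = config$clahe_clip_limit, keep.range = TRUE)
  t(as.matrix(out))
}

#' Denoise a micrograph with the full enhancement chain
#'
#' Stages run in a fixed order (Gaussian, standardization, 8-bit grayscale
#' mapping, non-local means, adaptive Wiener, CLAHE, guided filtering with
#' the CLAHE-enhanced image as guide and the Wiener output as input); each
#' stage can be toggled off in the [denoise_config()], supporting
#' denoised-versus-raw ablations. The result is mapped back to a float
#' image and re-standardized before entering the detector.
#'
#' @param micrograph A [cryo_micrograph()] or matrix.
#' @param config A [denoise_config()].
#' @return Same type as the input, same dimensions.
#' @export
denoise <- function(micrograph, config = denoise_config()) {
  m <- if (inherits(micrograph, "cryo_micrograph")) micrograph$pixels else micrograph
  stopifnot(all(is.finite(m)))
  st <- config$stages
  win <- max(config$nlmeans_search_window * st[["nlmeans"]],
             config$wiener_window * st[["wiener"]],
             (2 * config$guided_radius + 1) * st[["guided"]])
  if (win > 0 && (nrow(m) < win || ncol(m) < win))
    stop("image (", nrow(m), "x", ncol(m), ") smaller than the largest ",
         "filter window (", win, ")")
  if (st[["gaussian"]]) m <- gaussian_stage(m, config$gaussian_sigma)
  if (st[["normalize"]]) m <- normalize_standard(m)
  if (st[["grayscale"]]) m <- to_grayscale_uint(m)
  if (st[["nlmeans"]]) m <- nl_means(m, config$nlmeans_strength,
                                     config$nlmeans_template_window,
                                     config$nlmeans_search_window)
  if (st[["wiener"]]) m <- wiener_adaptive(m, config$wiener_window)
  if (st[["clahe"]] || st[["guided"]]) {
    rng <- range(m)
    m01 <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
    enhanced <- if (st[["clahe"]]) clahe_stage(m01, config) else m01
    m01 <- if (st[["guided"]]) {
      guided_filter(m01, guide = enhanced, radius = config$guided_radius,
                    epsilon = config$guided_epsilon)
    } else enhanced
    m <- m01 * if (diff(rng) > 0) diff(rng) else 1
    m <- m + rng[1]
  }
  if (st[["normalize"]]) m <- normalize_standard(m)
  if (inherits(micrograph, "cryo_micrograph")) {
    micrograph$pixels <- m
    micrograph
  } else m
}

gaussian_stage <- function(m, sigma) {
  as.matrix(EBImage::gblur(m, sigma = sigma))
}
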