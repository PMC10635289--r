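# Quadrant swap putting DC at the array center (even sides; inverse equals
# forward for even dimensions, which phantom sides always are here).
fftshift2 <- function(x) {
  n <- dim(x)
  h1 <- seq_len(n[1] / 2); h2 <- seq_len(n[2] / 2)
  x[c(setdiff(seq_len(n[1]), h1), h1), c(setdiff(seq_len(n[2]), h2), h2)]
}

# Unitary 2D DFT pair: forward F/N and adjoint (= exact conjugate transpose)
# unnormalized inverse FFT / N, with DC at the array center.
dft2_forward <- function(img) fftshift2(stats::fft(img)) / sqrt(length(img))
dft2_adjoint <- function(ksp) stats::fft(fftshift2(ksp), inverse = TRUE) / sqrt(length(ksp))

#' Phantom specification
#'
#' A square numerical phantom assembled from labeled geometric regions
#' (discs or axis-aligned rectangles), each carrying one
#' [parameter_vector()]. Background voxels have zero signal. Overlapping
#' regions resolve in declaration order: the later region wins.
#'
#' @param side Image side length in pixels.
#' @param regions List of regions; each is a list with `shape` (`"disc"` or
#'   `"rect"`), geometry (`center` + `radius` for discs, `xlim` + `ylim`
#'   for rectangles, in pixel coordinates) and `theta`, a
#'   [parameter_vector()].
#' @return Object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(side, regions) {
  stopifnot(side >= 2, length(regions) >= 1)
  for (rg in regions) {
    stopifnot(rg$shape %in% c("disc", "rect"), inherits(rg$theta, "parameter_vector"))
  }
  structure(list(side = as.integer(side), regions = regions),
            class = "phantom_spec")
}

#' Build a phantom's label map and voxel fingerprints
#'
#' Pure function of the specification and model: rasterizes the regions into
#' an integer label map (0 = background) and simulates one fingerprint per
#' region, returning also the full voxel-by-time signal matrix.
#'
#' @param spec A [phantom_spec()].
#' @param model A signal model object.
#' @return Object of class `"phantom"`: `labels` (`side x side` integer
#'   matrix), `fingerprints` (`N_T x n_regions` complex), `series`
#'   (`n_voxels x N_T` complex, voxels in column-major order), `spec`.
#' @export
make_phantom <- function(spec, model) {
  side <- spec$side
  xy <- expand.grid(x = seq_len(side), y = seq_len(side))
  labels <- matrix(0L, side, side)
  for (i in seq_along(spec$regions)) {
    rg <- spec$regions[[i]]
    inside <- if (rg$shape == "disc") {
      (xy$x - rg$center[1])^2 + (xy$y - rg$center[2])^2 <= rg$radius^2
    } else {
      xy$x >= rg$xlim[1] & xy$x <= rg$xlim[2] &
        xy$y >= rg$ylim[1] & xy$y <= rg$ylim[2]
    }
    labels[cbind(xy$x[inside], xy$y[inside])] <- i
  }
  fps <- vapply(spec$regions, function(rg) model_signal(model, rg$theta),
                complex(length(model_signal(model, spec$regions[[1]]$theta))))
  fps <- as_complex_matrix(fps)
  series <- matrix(0 + 0i, side * side, nrow(fps))
  lab_vec <- as.vector(labels)
  for (i in seq_along(spec$regions)) {
    sel <- lab_vec == i
    if (any(sel)) series[sel, ] <- matrix(fps[, i], sum(sel), nrow(fps), byrow = TRUE)
  }
  structure(list(labels = labels, fingerprints = fps, series = series,
                 spec = spec),
            class = "phantom")
}

#' True coefficient images of a phantom
#'
#' @param phantom A [make_phantom()] result.
#' @param basis A `subspace_basis`.
#' @return Complex array `side x side x N_c`.
#' @export
phantom_coefficients <- function(phantom, basis) {
  u <- basis_matrix(basis)
  cmat <- phantom$series %*% Conj(u)            # voxels x N_c
  array(cmat, dim = c(dim(phantom$labels), ncol(u)))
}

#' Per-frame Cartesian sampling masks
#'
#' Seeded variable-density random column sampling: every frame keeps the
#' central k-space column and one deterministic column that shifts by one
#' position per frame (so every column is revisited regularly and the
#' per-column frame subsets stay informative), plus further random columns
#' drawn without replacement with probability decaying with distance from
#' the center. Full columns mean the central row is covered by construction.
#'
#' @param side Image side length (even).
#' @param n_frames Number of time frames (fingerprint length).
#' @param accel Acceleration factor (1 = fully sampled).
#' @param seed Integer seed.
#' @return Logical array `side x side x n_frames`.
#' @export
make_sampling_masks <- function(side, n_frames, accel = 4, seed = 1L) {
  n_cols <- max(1L, round(side / accel))
  center <- side %/% 2 + 1L
  dist <- abs(seq_len(side) - center)
  # Gaussian density with a floor so outer k-space columns are visited often
  # enough to keep the normal operator well conditioned.
  prob <- 0.15 + exp(-(dist / (side / 4))^2)
  masks <- array(FALSE, dim = c(side, side, n_frames))
  withr::with_seed(seed, {
    for (t in seq_len(n_frames)) {
      cols <- unique(c(center, (t - 1L) %% side + 1L))[seq_len(min(2L, n_cols))]
      cols <- cols[!is.na(cols)]
      if (n_cols > length(cols)) {
        pool <- setdiff(seq_len(side), cols)
        cols <- c(cols, sample(pool, n_cols - length(cols), prob = prob[pool]))
      }
      masks[, cols, t] <- TRUE
    }
  })
  masks
}

#' Subspace forward model: coefficient images to sampled k-space
#'
#' Frame `t` of the data is the masked unitary 2D DFT of the image
#' `sum_k U[t, k] * c_k`; the operator is linear in the coefficient images.
#'
#' @param cimg Complex coefficient-image array `side x side x N_c`.
#' @param basis A `subspace_basis` (its `N_T` sets the number of frames).
#' @param masks Logical array from [make_sampling_masks()].
#' @return Object of class `"subsampled_kspace"`: `data` (complex array,
#'   zero where unsampled), `masks`, `side`.
#' @export
forward_model <- function(cimg, basis, masks) {
  u <- basis_matrix(basis)
  side <- dim(cimg)[1]
  n_t <- nrow(u)
  stopifnot(dim(cimg)[3] == ncol(u), dim(masks)[3] == n_t)
  cmat <- matrix(cimg, side * side, ncol(u))
  smat <- cmat %*% t(u)                          # voxels x N_T
  data <- array(0 + 0i, dim = c(side, side, n_t))
  for (t in seq_len(n_t)) {
    k <- dft2_forward(matrix(smat[, t], side, side))
    data[, , t] <- k * masks[, , t]
  }
  structure(list(data = data, masks = masks, side = side),
            class = "subsampled_kspace")
}

# Adjoint of forward_model, mapping sampled k-space to coefficient images.
adjoint_model <- function(ksp, basis) {
  u <- basis_matrix(basis)
  side <- ksp$side
  n_t <- nrow(u)
  smat <- matrix(0 + 0i, side * side, n_t)
  for (t in seq_len(n_t)) {
    smat[, t] <- as.vector(dft2_adjoint(ksp$data[, , t] * ksp$masks[, , t]))
  }
  array(smat %*% Conj(u), dim = c(side, side, ncol(u)))
}

#' Add complex Gaussian noise to sampled k-space
#'
#' Noise with standard deviation `sigma` per real/imaginary component is
#' added on the sampled locations only.
#'
#' @param ksp A `subsampled_kspace`.
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @return The noisy `subsampled_kspace`.
#' @export
add_kspace_noise <- function(ksp, noise, seed = 1L) {
  idx <- which(ksp$masks)
  eps <- withr::with_seed(seed, complex(
    real = stats::rnorm(length(idx), 0, noise$sigma),
    imaginary = stats::rnorm(length(idx), 0, noise$sigma)))
  ksp$data[idx] <- ksp$data[idx] + eps
  ksp
}

#' Conjugate-gradient subspace reconstruction
#'
#' Solves the normal equations `A^H A c = A^H y` of the subspace forward
#' model with the conjugate-gradient method, stopping at relative residual
#' `tol` or `n_iter` iterations. Ten consecutive residual increases raise a
#' divergence error.
#'
#' @param ksp A `subsampled_kspace`.
#' @param basis The `subspace_basis` used in the forward model.
#' @param n_iter Maximum iterations.
#' @param tol Relative residual tolerance.
#' @return Object of class `"subspace_recon"`: `cimg` (complex
#'   `side x side x N_c`), `residuals` (per-iteration relative residual),
#'   `converged`.
#' @export
cg_subspace_recon <- function(ksp, basis, n_iter = 50L, tol = 1e-8) {
  normal_op <- function(x) adjoint_model(forward_model(x, basis, ksp$masks), basis)
  b <- adjoint_model(ksp, basis)
  x <- array(0 + 0i, dim = dim(b))
  r <- b
  p <- r
  rr <- sum(Mod(r)^2)
  b_norm <- sqrt(sum(Mod(b)^2))
  if (b_norm == 0) {
    return(structure(list(cimg = x, residuals = numeric(0), converged = TRUE),
                     class = "subspace_recon"))
  }
  residuals <- numeric(0)
  n_up <- 0L
  best <- Inf
  for (it in seq_len(n_iter)) {
    ap <- normal_op(p)
    alpha <- rr / Re(sum(Conj(p) * ap))
    x <- x + alpha * p
    r <- r - alpha * ap
    rr_new <- sum(Mod(r)^2)
    rel <- sqrt(rr_new) / b_norm
    # divergence = sustained growth well above the best residual seen (plain
    # per-iteration comparisons would trip on round-off at the residual floor)
    if (rel > 1.5 * best) {
      n_up <- n_up + 1L
      if (n_up >= 10L) abort("conjugate gradient diverged")
    } else n_up <- 0L
    best <- min(best, rel)
    residuals <- c(residuals, rel)
    if (rel < tol) {
      return(structure(list(cimg = x, residuals = residuals, converged = TRUE),
                       class = "subspace_recon"))
    }
    beta <- rr_new / rr
    p <- r + beta * p
    rr <- rr_new
  }
  structure(list(cimg = x, residuals = residuals, converged = FALSE),
            class = "subspace_recon")
}

#' Voxel-wise dictionary matching of coefficient images
#'
#' Applies [dictionary_match()] to every voxel's coefficient vector;
#' voxels whose coefficient energy falls below `mask_rel` times the maximum
#' are treated as background and masked out.
#'
#' @param cimg Complex coefficient-image array (`side x side x N_c`) — e.g.
#'   the `cimg` field of a [cg_subspace_recon()] result.
#' @param cdict A [compress_dictionary()] result using the same basis.
#' @param mask_rel Relative coefficient-magnitude threshold for background
#'   masking (default 0.1).
#' @return Object of class `"parameter_maps"`: matrices `t1_ms`, `t2_ms`,
#'   `m0_mod` (NA on background) and the logical `foreground` mask.
#' @export
fit_maps <- function(cimg, cdict, mask_rel = 0.1) {
  side <- dim(cimg)[1]
  cmat <- matrix(cimg, side * side, dim(cimg)[3])
  energy <- sqrt(rowSums(Mod(cmat)^2))
  fg <- energy > mask_rel * max(energy)
  t1 <- t2 <- m0 <- rep(NA_real_, side * side)
  for (v in which(fg)) {
    m <- dictionary_match(cmat[v, ], cdict)
    t1[v] <- 1000 / m$theta_hat$r1[[1]]
    t2[v] <- 1000 / m$theta_hat$r2[[1]]
    m0[v] <- Mod(m$m0_hat)
  }
  structure(
    list(t1_ms = matrix(t1, side, side), t2_ms = matrix(t2, side, side),
         m0_mod = matrix(m0, side, side),
         foreground = matrix(fg, side, side)),
    class = "parameter_maps"
  )
}

#' @export
tidy.parameter_maps <- function(x, ...) {
  side <- nrow(x$t1_ms)
  tibble(x_pix = rep(seq_len(side), side),
         y_pix = rep(seq_len(side), each = side),
         t1_ms = as.vector(x$t1_ms), t2_ms = as.vector(x$t2_ms),
         m0_mod = as.vector(x$m0_mod),
         foreground = as.vector(x$foreground))
}

#' Raster plot of fitted parameter maps
#'
#' @param object A `parameter_maps` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.parameter_maps <- function(object, ...) {
  d <- tidy(object) |>
    tidyr::pivot_longer(c("t1_ms", "t2_ms"), names_to = "map", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x_pix, y = .data$y_pix,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~map) +
    ggplot2::scale_fill_viridis_c(na.value = "black") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "ms")
}
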