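#' Shannon entropy of a beamformed image
#'
#' The image is normalized, histogrammed into `n_bins` equal-width bins,
#' and scored with `H = -sum(p_i log2 p_i)` (with `0 log 0 := 0`). The
#' result lies in `[0, log2(n_bins)]` bits and is invariant under positive
#' rescaling of the image (the normalization absorbs gain). By default the
#' histogram is taken over the max-normalized linear envelope: mis-delayed
#' summation loses coherent amplitude, flattening the envelope's amplitude
#' distribution relative to a well-focused reconstruction, so across
#' assumed array shapes the shape closest to the truth tends to give the
#' largest entropy — the property the shape optimizer exploits.
#' `on = "display"` histograms the log-compressed (60 dB) pixels instead,
#' for comparison.
#'
#' @param img A `bf_image`, a [scan_convert()] raster, or a numeric matrix
#'   of non-negative envelope values.
#' @param n_bins Histogram bin count (>= 2), default 256.
#' @param on Which pixel values to histogram: `"envelope"` (max-normalized
#'   linear envelope; default) or `"display"` (log-compressed at 60 dB).
#' @return Entropy in bits.
#' @examples
#' image_entropy(matrix(runif(1e4), 100))
#' @export
image_entropy <- function(img, n_bins = 256L, on = c("envelope", "display")) {
  on <- match.arg(on)
  if (n_bins < 2) stop_flexbeam("n_bins must be >= 2", "input_error")
  v <- if (inherits(img, "bf_image")) {
    if (on == "display") -envelope_display(img)$display else img$envelope
  } else if (inherits(img, "raster_image")) {
    px <- if (on == "display") -envelope_display(img)$display else img$pixels
    px[img$mask]
  } else {
    if (on == "display") stop_flexbeam("display entropy needs an image object",
                                       "input_error")
    as.numeric(img)
  }
  v <- as.numeric(v)
  v <- v[is.finite(v)]
  if (length(v) == 0) stop_flexbeam("image is empty", "input_error")
  m <- max(v)
  if (m <= 0) return(0)
  idx <- pmin(floor(v / m * n_bins) + 1L, n_bins)
  p <- tabulate(idx, n_bins) / length(idx)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' External angles of an arbitrary shape
#'
#' Recovers the K - 1 external angles from a shape: the first K - 2 are the
#' differences of successive chord direction angles; the last one is the
#' bend from the final chord to the final element's tangent (only that
#' element's scan-line direction, not any position, depends on it). Inverse
#' of [polyline_shape()] up to the rigid frame.
#'
#' @param shape A `flex_shape`.
#' @return Numeric vector of K - 1 external angles, rad.
#' @export
params_from_shape <- function(shape) {
  dx <- diff(shape$x); dz <- diff(shape$z)
  chord <- atan2(dz, dx)
  t_last <- -shape$alpha[nrow(shape)]
  diff(c(chord, t_last))
}

# One objective evaluation: params -> polyline shape -> grid -> DAS ->
# entropy. Grid decimation (every `decimate`-th line and depth) trades
# fidelity for speed during optimization only.
entropy_objective <- function(rf, depth_range, depth_step, n_bins, decimate,
                              on = "envelope") {
  spec <- rf$spec
  function(params) {
    shape <- polyline_shape(params, spec)
    grid <- build_grid(shape, depth_range, depth_step)
    if (decimate > 1) {
      keep_l <- seq(1, grid$L, by = decimate)
      keep_d <- seq(1, grid$D, by = decimate)
      fx <- matrix(grid$focal[, 1], grid$D, grid$L)[keep_d, keep_l]
      fz <- matrix(grid$focal[, 2], grid$D, grid$L)[keep_d, keep_l]
      grid$origins <- grid$origins[keep_l, , drop = FALSE]
      grid$directions <- grid$directions[keep_l, , drop = FALSE]
      grid$angles <- grid$angles[keep_l]
      grid$depths <- grid$depths[keep_d]
      grid$L <- length(keep_l); grid$D <- length(keep_d)
      grid$focal <- cbind(as.numeric(fx), as.numeric(fz))
    }
    img <- das(rf, shape, grid)
    list(entropy = image_entropy(img, n_bins, on), shape = shape)
  }
}

#' Shape-error versus image-entropy scan
#'
#' Draws random shape assumptions around the true shape (independent uniform
#' per-angle perturbations up to `perturb_scale`), beamforms the same RF
#' data under each assumption, and records the element-position mean
#' absolute error together with the image entropy. On speckle data the two
#' are negatively rank-correlated: the entropy tends to be larger when the
#' shape error is smaller, which justifies entropy *maximization* as the
#' autofocus criterion.
#'
#' @param rf RF data whose true acquisition shape is known.
#' @param true_shape The shape that produced `rf`.
#' @param n_assumptions Number of random assumptions.
#' @param perturb_scale Per-angle uniform perturbation half-width, rad.
#' @param seed Integer seed.
#' @param depth_range,depth_step Imaging grid settings (see [build_grid()]).
#' @param n_bins Entropy histogram bins.
#' @param on Entropy pixel domain (see [image_entropy()]).
#' @return Tibble with columns `assumption`, `mae_mm`, `entropy_bits`.
#' @export
entropy_error_scan <- function(rf, true_shape, n_assumptions = 100,
                               perturb_scale = pi / 720, seed = 1L,
                               depth_range = c(5, 60), depth_step = 0.154,
                               n_bins = 256L, on = c("envelope", "display")) {
  on <- match.arg(on)
  p0 <- params_from_shape(true_shape)
  obj <- entropy_objective(rf, depth_range, depth_step, n_bins, 1L, on)
  set.seed(seed)
  purrr::map_dfr(seq_len(n_assumptions), function(i) {
    p <- p0 + runif(length(p0), -perturb_scale, perturb_scale)
    ev <- obj(p)
    tibble::tibble(assumption = i,
                   mae_mm = shape_mae(true_shape, ev$shape),
                   entropy_bits = ev$entropy)
  })
}

# Cubic radial-basis surrogate with linear tail, fitted to all evaluated
# points; used to rank candidate shapes so that only the most promising one
# costs a full DAS reconstruction.
rbf_fit <- function(X, y) {
  n <- nrow(X)
  r <- as.matrix(stats::dist(X))
  Phi <- r^3
  P <- cbind(1, X)
  A <- rbind(cbind(Phi + diag(1e-8, n), P),
             cbind(t(P), matrix(0, ncol(P), ncol(P))))
  rhs <- c(y, numeric(ncol(P)))
  co <- tryCatch(solve(A, rhs), error = function(e) NULL)
  if (is.null(co)) return(NULL)
  list(X = X, w = co[seq_len(n)], v = co[-seq_len(n)])
}

rbf_predict <- function(fit, Xc) {
  r2 <- outer(rowSums(Xc^2), rowSums(fit$X^2), "+") - 2 * Xc %*% t(fit$X)
  Phi <- pmax(r2, 0)^1.5
  as.numeric(Phi %*% fit$w + cbind(1, Xc) %*% fit$v)
}

#' Entropy-driven global shape optimization
#'
#' Searches the external-angle parameters within the box
#' `[init - bound_halfwidth, init + bound_halfwidth]` (per coordinate) for
#' the shape whose delay-and-sum image has maximal Shannon entropy. The
#' default box half-width pi/720 rad keeps the shape smooth and continuous,
#' and the search budget defaults to 200 objective evaluations, each one a
#' full beamforming pass.
#'
#' The search is a seeded, derivative-free, surrogate-assisted stochastic
#' search: batches of candidate parameter vectors are drawn around the
#' incumbent at an adaptive scale (clipped to the box), ranked by a cubic
#' radial-basis surrogate fitted to all evaluated points, and only the
#' top-ranked candidate is evaluated; the proposal scale grows on success,
#' shrinks on failure, and is re-expanded with a uniform exploration draw
#' after prolonged stagnation (periodic restart). The best-so-far objective
#' is non-decreasing along the trace, every evaluated point respects the
#' bounds, and reruns with the same seed reproduce the trace exactly.
#'
#' @param rf RF channel data.
#' @param init Initial external angles (length K - 1), typically
#'   [params_from_arc()] of the optical radius estimate.
#' @param bound_halfwidth Box half-width per coordinate, rad.
#' @param max_evals Objective evaluation budget.
#' @param seed Integer seed.
#' @param direction `"maximize"` (the autofocus principle) or `"minimize"`
#'   (control experiment; drives the shape away from focus).
#' @param true_shape Optional ground truth; if given, the trace records the
#'   element-position MAE of every evaluated shape.
#' @param depth_range,depth_step Imaging grid settings.
#' @param n_bins Entropy histogram bins.
#' @param decimate Grid decimation factor during optimization (1 = off).
#' @param on Entropy pixel domain (see [image_entropy()]).
#' @return Object of class `shape_opt`: list with `best_params`,
#'   `best_entropy`, `best_shape`, `trace` (tibble `eval`, `entropy_bits`,
#'   `best_entropy_bits`, `mae_mm` if truth known), `evaluations`, `seed`,
#'   `direction`, `bounds`.
#' @export
optimize_shape <- function(rf, init, bound_halfwidth = pi / 720,
                           max_evals = 200L, seed = 1L,
                           direction = c("maximize", "minimize"),
                           true_shape = NULL,
                           depth_range = c(5, 60), depth_step = 0.154,
                           n_bins = 256L, decimate = 1L,
                           on = c("envelope", "display")) {
  direction <- match.arg(direction)
  on <- match.arg(on)
  d <- rf$spec$K - 1L
  if (length(init) != d)
    stop_flexbeam(sprintf("init must have length %d", d), "dim_error")
  if (bound_halfwidth <= 0 || max_evals < 1)
    stop_flexbeam("need bound_halfwidth > 0 and max_evals >= 1", "input_error")
  lb <- init - bound_halfwidth; ub <- init + bound_halfwidth
  sgn <- if (direction == "maximize") 1 else -1
  obj <- entropy_objective(rf, depth_range, depth_step, n_bins, decimate, on)

  set.seed(seed)
  X <- matrix(NA_real_, max_evals, d)
  ent <- numeric(max_evals)
  mae <- rep(NA_real_, max_evals)
  evaluate <- function(i, p) {
    ev <- obj(p)
    X[i, ] <<- p
    ent[i] <<- ev$entropy
    if (!is.null(true_shape)) mae[i] <<- shape_mae(true_shape, ev$shape)
    sgn * ev$entropy
  }

  f_best <- evaluate(1L, init)
  best <- init
  best_eval <- 1L
  sigma <- bound_halfwidth / 2
  stall <- 0L
  n_ev <- 1L
  while (n_ev < max_evals) {
    n_ev <- n_ev + 1L
    if (stall >= 40L) {            # periodic restart: exploration draw
      cand <- runif(d, lb, ub)
      sigma <- bound_halfwidth / 2
      stall <- 0L
    } else {
      n_cand <- 30L
      C <- matrix(rnorm(n_cand * d, 0, sigma), n_cand, d, byrow = TRUE)
      C <- sweep(C, 2, best, "+")
      C <- pmin(pmax(C, matrix(lb, n_cand, d, byrow = TRUE)),
                matrix(ub, n_cand, d, byrow = TRUE))
      pick <- 1L
      if (n_ev > 10L) {
        fit <- rbf_fit(X[seq_len(n_ev - 1L), , drop = FALSE],
                       sgn * ent[seq_len(n_ev - 1L)])
        if (!is.null(fit)) pick <- which.max(rbf_predict(fit, C))
      }
      cand <- C[pick, ]
    }
    f <- evaluate(n_ev, cand)
    if (f > f_best) {
      f_best <- f; best <- cand; best_eval <- n_ev
      sigma <- min(sigma * 1.4, bound_halfwidth)
      stall <- 0L
    } else {
      sigma <- max(sigma * 0.88, bound_halfwidth / 200)
      stall <- stall + 1L
    }
  }

  run_best <- sgn * cummax(sgn * ent[seq_len(n_ev)])
  trace <- tibble::tibble(eval = seq_len(n_ev),
                          entropy_bits = ent[seq_len(n_ev)],
                          best_entropy_bits = run_best)
  if (!is.null(true_shape)) trace$mae_mm <- mae[seq_len(n_ev)]
  structure(list(best_params = best,
                 best_entropy = sgn * f_best,
                 best_shape = polyline_shape(best, rf$spec),
                 trace = trace, evaluations = n_ev, best_eval = best_eval,
                 seed = seed,
                 direction = direction,
                 bounds = list(lb = lb, ub = ub)),
            class = "shape_opt")
}

#' @export
print.shape_opt <- function(x, ...) {
  cat(sprintf("<shape_opt> %s entropy: best %.4f bits after %d evaluations (seed %d)\n",
              x$direction, x$best_entropy, x$evaluations, x$seed))
  invisible(x)
}

#' @export
tidy.shape_opt <- function(x, ...) x$trace

#' @export
glance.shape_opt <- function(x, ...) {
  tibble::tibble(
    best_entropy_bits = x$best_entropy,
    evaluations = x$evaluations,
    initial_mae_mm = if ("mae_mm" %in% names(x$trace)) x$trace$mae_mm[1] else NA_real_,
    final_mae_mm = if ("mae_mm" %in% names(x$trace))
      x$trace$mae_mm[x$best_eval] else NA_real_,
    direction = x$direction, seed = x$seed)
}

#' @export
autoplot.shape_opt <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$eval)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$entropy_bits),
                        size = 0.6, alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$best_entropy_bits),
                       colour = "firebrick") +
    ggplot2::labs(x = "objective evaluation", y = "image entropy (bits)",
                  title = sprintf("Entropy %s trace", object$direction))
}

#' Write the optimization trace as CSV
#'
#' Columns `eval,entropy_bits,mae_mm_if_truth_known`.
#' @param result A [optimize_shape()] result.
#' @param path File path.
#' @export
write_trace_csv <- function(result, path) {
  tr <- result$trace
  df <- data.frame(eval = tr$eval, entropy_bits = tr$entropy_bits,
                   mae_mm_if_truth_known =
                     if ("mae_mm" %in% names(tr)) tr$mae_mm else NA_real_)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
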