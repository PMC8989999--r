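#' Image specification for the rod-cell micrograph simulator
#'
#' @param image_size image side length in pixels (square image).
#' @param pixel_size pixel size in micrometers/pixel.
#' @param n_cells number of rods to place.
#' @param cell_length_range,cell_width_range rod pole-to-pole length and
#'   width ranges in micrometers.
#' @param fg,bg interior and background intensity levels.
#' @param psf_sigma Gaussian point-spread-function sigma in pixels (0 = no
#'   blurring).
#' @param noise_model `"none"`, `"gaussian"` or `"poisson"`.
#' @param noise_sd standard deviation for the Gaussian noise model.
#' @param margin minimum gap between rods and to the border, in pixels.
#' @param seed integer RNG seed.
#' @return an object of class `"image_spec"`.
#' @export
image_spec <- function(image_size = 256, pixel_size = 0.1, n_cells = 5,
                       cell_length_range = c(2, 4),
                       cell_width_range = c(0.6, 0.9),
                       fg = 100, bg = 10, psf_sigma = 0,
                       noise_model = c("none", "gaussian", "poisson"),
                       noise_sd = 1, margin = 3, seed = 1) {
  noise_model <- match.arg(noise_model)
  if (image_size < 8) stop("`image_size` too small")
  if (pixel_size <= 0) stop("`pixel_size` must be > 0")
  if (any(cell_length_range <= 0) || any(cell_width_range <= 0))
    stop("cell size ranges must be positive")
  if (diff(cell_length_range) < 0 || diff(cell_width_range) < 0)
    stop("ranges must be increasing")
  structure(list(image_size = as.integer(image_size), pixel_size = pixel_size,
                 n_cells = as.integer(n_cells),
                 cell_length_range = cell_length_range,
                 cell_width_range = cell_width_range,
                 fg = fg, bg = bg, psf_sigma = psf_sigma,
                 noise_model = noise_model, noise_sd = noise_sd,
                 margin = margin, seed = as.integer(seed)),
            class = "image_spec")
}

## squared distance from pixel grid points to a segment (x1,y1)-(x2,y2)
.dist2_segment <- function(px, py, x1, y1, x2, y2) {
  vx <- x2 - x1; vy <- y2 - y1
  l2 <- vx * vx + vy * vy
  if (l2 == 0) return((px - x1)^2 + (py - y1)^2)
  t <- pmin(1, pmax(0, ((px - x1) * vx + (py - y1) * vy) / l2))
  (px - (x1 + t * vx))^2 + (py - (y1 + t * vy))^2
}

#' Render a synthetic micrograph of non-overlapping rod-shaped cells
#'
#' Cells are spherocylinders (rectangles with semicircular caps) with
#' uniform interior intensity, rasterized onto a background level,
#' optionally blurred with a Gaussian PSF and corrupted with Gaussian or
#' Poisson noise. Placement retries until rods neither overlap nor touch
#' the border; an error is raised if a rod cannot be placed within a
#' bounded number of retries.
#'
#' @param spec an [image_spec()].
#' @return a list with `image` (numeric matrix, rows = y), and `cells`, the
#'   ground-truth data frame (`cell_id`, centroid `x_px`/`y_px`, `length_um`
#'   pole-to-pole, `width_um`, `theta` orientation in radians).
#' @export
simulate_images <- function(spec) {
  stopifnot(inherits(spec, "image_spec"))
  set.seed(spec$seed)
  sz <- spec$image_size
  px_per_um <- 1 / spec$pixel_size
  placed <- list()
  max_try <- 2000L
  for (i in seq_len(spec$n_cells)) {
    ok <- FALSE
    for (try in seq_len(max_try)) {
      len <- stats::runif(1, spec$cell_length_range[1], spec$cell_length_range[2])
      wid <- stats::runif(1, spec$cell_width_range[1], spec$cell_width_range[2])
      th <- stats::runif(1, 0, pi)
      ax_px <- (len - wid) * px_per_um    # medial-axis (segment) length
      r_px <- wid / 2 * px_per_um
      pad <- ax_px / 2 + r_px + spec$margin
      if (2 * pad >= sz) next
      cx <- stats::runif(1, pad, sz - pad)
      cy <- stats::runif(1, pad, sz - pad)
      x1 <- cx - cos(th) * ax_px / 2; y1 <- cy - sin(th) * ax_px / 2
      x2 <- cx + cos(th) * ax_px / 2; y2 <- cy + sin(th) * ax_px / 2
      clash <- FALSE
      for (p in placed) {
        ## min distance between the two axis segments must exceed the radii
        d2 <- min(.dist2_segment(c(x1, x2, (x1 + x2) / 2), c(y1, y2, (y1 + y2) / 2),
                                 p$x1, p$y1, p$x2, p$y2),
                  .dist2_segment(c(p$x1, p$x2, (p$x1 + p$x2) / 2),
                                 c(p$y1, p$y2, (p$y1 + p$y2) / 2),
                                 x1, y1, x2, y2))
        if (sqrt(d2) < r_px + p$r_px + spec$margin) { clash <- TRUE; break }
      }
      if (!clash) {
        placed[[i]] <- list(x1 = x1, y1 = y1, x2 = x2, y2 = y2, r_px = r_px,
                            cx = cx, cy = cy, len = len, wid = wid, th = th)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place cell ", i, " without overlap after ",
                  max_try, " retries; reduce n_cells or cell sizes")
  }
  img <- matrix(spec$bg, sz, sz)
  xg <- matrix(rep(seq_len(sz), each = sz), sz, sz)   # column index
  yg <- matrix(rep(seq_len(sz), times = sz), sz, sz)  # row index
  for (p in placed) {
    d2 <- .dist2_segment(xg, yg, p$x1, p$y1, p$x2, p$y2)
    img[d2 <= p$r_px^2] <- spec$fg
  }
  if (spec$psf_sigma > 0) {
    bw <- 2L * ceiling(3 * spec$psf_sigma) + 1L
    k <- EBImage::makeBrush(bw, shape = "gaussian", sigma = spec$psf_sigma)
    img <- as.matrix(EBImage::filter2(EBImage::Image(img), k))
  }
  img <- switch(spec$noise_model,
    none = img,
    gaussian = img + stats::rnorm(length(img), 0, spec$noise_sd),
    poisson = matrix(stats::rpois(length(img), pmax(img, 0)),
                     nrow(img), ncol(img)))
  cells <- if (length(placed)) data.frame(
    cell_id = seq_along(placed),
    x_px = vapply(placed, `[[`, 0, "cx"),
    y_px = vapply(placed, `[[`, 0, "cy"),
    length_um = vapply(placed, `[[`, 0, "len"),
    width_um = vapply(placed, `[[`, 0, "wid"),
    theta = vapply(placed, `[[`, 0, "th"))
  else data.frame(cell_id = integer(), x_px = numeric(), y_px = numeric(),
                  length_um = numeric(), width_um = numeric(), theta = numeric())
  list(image = img, cells = cells)
}
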