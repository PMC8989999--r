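#' Shape gates for segmented cells
#'
#' Closed-interval filters on the shape descriptors of segmented cells,
#' with defaults matching the rod-shaped-bacteria gates used for E. coli:
#' area 0.1 µm² to unbounded, length 1.2–5 µm, width 0.1–1 µm, curvature
#' 0–0.15 and angularity 0–0.25. Any gate can be disabled by widening its
#' interval.
#'
#' @param area_range µm², `c(min, max)`; default `c(0.1, Inf)`.
#' @param length_range µm; default `c(1.2, 5)`.
#' @param width_range µm; default `c(0.1, 1)`.
#' @param curvature_range unitless; default `c(0, 0.15)`.
#' @param angularity_range unitless; default `c(0, 0.25)`.
#' @return an object of class `"shape_gates"`.
#' @export
shape_gates <- function(area_range = c(0.1, Inf), length_range = c(1.2, 5),
                        width_range = c(0.1, 1), curvature_range = c(0, 0.15),
                        angularity_range = c(0, 0.25)) {
  g <- list(area = area_range, length = length_range, width = width_range,
            curvature = curvature_range, angularity = angularity_range)
  for (nm in names(g)) {
    r <- g[[nm]]
    if (length(r) != 2L || r[1] > r[2] || r[1] < 0)
      stop("gate `", nm, "` must be c(min, max) with 0 <= min <= max")
  }
  structure(g, class = "shape_gates")
}

#' Segment rod-shaped cells from a grayscale micrograph
#'
#' Otsu threshold on the intensity histogram, hole filling, connected-
#' component labelling, and removal of components touching the image
#' border (their shape descriptors would be truncated).
#'
#' @param image 2-D numeric matrix (grayscale micrograph).
#' @param pixel_size µm/pixel, `> 0`.
#' @param min_px discard components smaller than this many pixels
#'   (speckle guard); default 4.
#' @return a list of logical mask matrices (same dimensions as `image`),
#'   one per retained cell; an empty list for a flat or empty image.
#' @export
segment_cells <- function(image, pixel_size = 0.1, min_px = 4L) {
  stopifnot(is.matrix(image), pixel_size > 0)
  rng <- range(image)
  if (diff(rng) == 0) return(list())
  norm <- (image - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(norm))
  mask <- norm > th
  mask <- EBImage::fillHull(EBImage::Image(mask)) > 0
  lab <- EBImage::bwlabel(EBImage::Image(mask))
  lab <- as.matrix(EBImage::imageData(lab))
  if (max(lab) == 0) return(list())
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  keep <- setdiff(seq_len(max(lab)), border)
  masks <- lapply(keep, function(i) lab == i)
  masks[vapply(masks, sum, 0L) >= min_px]
}

## 8-neighbourhood circular order P2..P9 (N, NE, E, SE, S, SW, W, NW) as
## row/col offsets
.zs_off <- cbind(dr = c(-1, -1, 0, 1, 1, 1, 0, -1),
                 dc = c(0, 1, 1, 1, 0, -1, -1, -1))

## Zhang-Suen thinning to a 1-px medial axis; operates on a logical matrix
.thin_mask <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask * 1L
  nb <- function(m, k) {
    o <- .zs_off[k, ]
    m[(2 + o[1]):(nrow(m) - 1 + o[1]), (2 + o[2]):(ncol(m) - 1 + o[2])]
  }
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      P <- lapply(1:8, function(k) nb(m, k))
      core <- m[2:(nrow(m) - 1), 2:(ncol(m) - 1)]
      B <- Reduce(`+`, P)
      ring <- c(P, P[1])
      A <- Reduce(`+`, lapply(1:8, function(k) (ring[[k]] == 0) & (ring[[k + 1]] == 1)))
      if (phase == 1) {
        c1 <- P[[1]] * P[[3]] * P[[5]]; c2 <- P[[3]] * P[[5]] * P[[7]]
      } else {
        c1 <- P[[1]] * P[[3]] * P[[7]]; c2 <- P[[1]] * P[[5]] * P[[7]]
      }
      del <- core == 1 & B >= 2 & B <= 6 & A == 1 & c1 == 0 & c2 == 0
      if (any(del)) {
        core[del] <- 0L
        m[2:(nrow(m) - 1), 2:(ncol(m) - 1)] <- core
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m[2:(nrow(m) - 1), 2:(ncol(m) - 1)] == 1L
}

## order skeleton pixels along the longest path between endpoints;
## returns an n x 2 matrix of (row, col)
.axis_path <- function(skel) {
  pts <- which(skel, arr.ind = TRUE)
  n <- nrow(pts)
  if (n == 1L) return(pts)
  key <- paste(pts[, 1], pts[, 2])
  idx <- seq_len(n)
  names(idx) <- key
  adj <- lapply(seq_len(n), function(i) {
    nbr <- cbind(pts[i, 1] + .zs_off[, 1], pts[i, 2] + .zs_off[, 2])
    hits <- idx[paste(nbr[, 1], nbr[, 2])]
    hits[!is.na(hits)]
  })
  bfs_far <- function(start) {
    dist <- rep(NA_integer_, n); prev <- rep(NA_integer_, n)
    dist[start] <- 0L
    q <- start
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (w in adj[[v]]) if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L; prev[w] <- v; q <- c(q, w)
      }
    }
    far <- which.max(dist)
    list(far = far, prev = prev)
  }
  a <- bfs_far(1L)$far
  b <- bfs_far(a)
  path <- b$far
  while (!is.na(b$prev[path[1]])) path <- c(b$prev[path[1]], path)
  pts[path, , drop = FALSE]
}

#' Measure shape descriptors of one segmented cell
#'
#' Area is the pixel count scaled by the pixel area. The medial axis is
#' obtained by Zhang-Suen thinning and ordered as the longest path through
#' the skeleton. Width is twice the mean distance-transform value along
#' the axis; length is the axis arc length plus one width (spherocylinder
#' cap correction). Curvature is `1 - chord/arc` of the axis; angularity is
#' the mean absolute turning angle per step along the axis, divided by pi.
#'
#' @param mask logical matrix, one connected component.
#' @param pixel_size µm/pixel.
#' @param field field-of-view id carried into the result.
#' @return one-row data frame: `area`, `length`, `width` (µm-based),
#'   `curvature`, `angularity`, centroid `x_px`/`y_px`, `field`.
#' @export
measure_shape <- function(mask, pixel_size = 0.1, field = 1L) {
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  npx <- sum(mask)
  if (npx < 4L) stop("mask smaller than 4 px: degenerate skeleton")
  area <- npx * pixel_size^2
  pts_all <- which(mask, arr.ind = TRUE)
  cx <- mean(pts_all[, 2]); cy <- mean(pts_all[, 1])
  skel <- .thin_mask(mask)
  if (!any(skel)) { # thinning can erase tiny blobs; fall back to centroid px
    skel <- matrix(FALSE, nrow(mask), ncol(mask))
    skel[round(cy), round(cx)] <- TRUE
  }
  path <- .axis_path(skel)
  dm <- as.matrix(EBImage::distmap(EBImage::Image(mask * 1)))
  width <- 2 * mean(dm[path]) * pixel_size
  ## cap correction: march from each axis endpoint along the local axis
  ## direction to the mask boundary, so pole-to-pole length is recovered
  ## wherever thinning stopped within the caps
  march <- function(from, towards) {
    v <- from - towards
    nv <- sqrt(sum(v^2))
    if (nv == 0) return(0)
    v <- v / nv
    s <- 0
    repeat {
      s2 <- s + 0.25
      r <- round(from[1] + v[1] * s2); c <- round(from[2] + v[2] * s2)
      if (r < 1 || c < 1 || r > nrow(mask) || c > ncol(mask) || !mask[r, c])
        break
      s <- s2
    }
    s
  }
  np <- nrow(path)
  cap <- if (np >= 2) {
    k <- min(5L, np - 1L)
    (march(path[1, ], path[1 + k, ]) + march(path[np, ], path[np - k, ])) *
      pixel_size
  } else width
  if (np >= 2) {
    ## subsample the pixel path before measuring: the raw 8-connected
    ## staircase inflates arc length and turning angles for tilted rods
    sub <- path[unique(c(seq(1L, np, by = 3L), np)), , drop = FALSE]
    steps <- diff(sub)
    steplen <- sqrt(rowSums(steps^2))
    arc <- sum(steplen)
    chord <- sqrt(sum((sub[nrow(sub), ] - sub[1, ])^2))
    curvature <- if (arc > 0) 1 - chord / arc else 0
    if (nrow(steps) >= 2) {
      ang <- atan2(steps[, 1], steps[, 2])
      turn <- diff(ang)
      turn <- atan2(sin(turn), cos(turn))  # wrap to (-pi, pi]
      angularity <- mean(abs(turn)) / pi
    } else angularity <- 0
  } else {
    arc <- 0; curvature <- 0; angularity <- 0
  }
  len <- arc * pixel_size + cap
  ## thinning can collapse the skeleton of steeply diagonal rods; if the
  ## axis-derived length falls far short of the mask's principal-axis
  ## extent, fall back to that extent (straight-axis assumption)
  pc <- stats::prcomp(pts_all, center = TRUE)
  ext <- (diff(range(pc$x[, 1])) + 1) * pixel_size
  if (len < 0.7 * ext) {
    len <- ext
    curvature <- 0
    angularity <- 0
  }
  data.frame(area = area, length = len, width = width,
             curvature = curvature, angularity = angularity,
             x_px = cx, y_px = cy, field = field)
}

#' Filter measured cells with shape gates
#'
#' Keeps cells whose every descriptor lies inside its closed gate interval.
#' Per-gate rejection counts (a cell failing several gates is counted under
#' each) are attached as attribute `"rejections"`.
#'
#' @param shapes data frame with columns `area`, `length`, `width`,
#'   `curvature`, `angularity` (as from [measure_shape()]).
#' @param gates a [shape_gates()] object.
#' @return the surviving rows, with attribute `rejections` (named integer
#'   vector) and `n_in`.
#' @export
apply_gates <- function(shapes, gates = shape_gates()) {
  stopifnot(inherits(gates, "shape_gates"), is.data.frame(shapes))
  need <- names(unclass(gates))
  miss <- setdiff(need, names(shapes))
  if (length(miss)) stop("missing shape columns: ", paste(miss, collapse = ", "))
  keep <- rep(TRUE, nrow(shapes))
  rej <- integer(length(need)); names(rej) <- need
  for (nm in need) {
    r <- gates[[nm]]
    ok <- shapes[[nm]] >= r[1] & shapes[[nm]] <= r[2]
    rej[nm] <- sum(!ok)
    keep <- keep & ok
  }
  out <- shapes[keep, , drop = FALSE]
  attr(out, "rejections") <- rej
  attr(out, "n_in") <- nrow(shapes)
  out
}

#' Extract per-cell mean intensities from channel images
#'
#' @param masks list of logical masks (as from [segment_cells()]).
#' @param channel_images named list of numeric matrices, one per channel,
#'   same dimensions as the masks.
#' @param field field-of-view id.
#' @return data frame: `cell_id`, `field`, one `<channel>_raw` column per
#'   channel holding the mean intensity over the mask pixels.
#' @export
extract_intensities <- function(masks, channel_images, field = 1L) {
  stopifnot(is.list(channel_images), !is.null(names(channel_images)))
  for (ch in names(channel_images)) {
    if (length(masks) && !identical(dim(channel_images[[ch]]), dim(masks[[1]])))
      stop("channel `", ch, "` image dimensions do not match the masks")
  }
  out <- data.frame(cell_id = seq_along(masks), field = field)
  for (ch in names(channel_images)) {
    img <- channel_images[[ch]]
    out[[paste0(ch, "_raw")]] <- vapply(masks, function(m) mean(img[m]),
                                        numeric(1))
  }
  out
}
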