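#' Frame geometry
#'
#' Width and height of the video frame in pixels, plus the frame rate of the
#' extracted sequence. The origin is the top-left corner, x rightward,
#' y downward. The default 6 fps matches the extraction rate used for
#' robotic-surgery video datasets (the greatest common divisor of the common
#' 24 and 30 fps camera rates).
#'
#' @param width Frame width in pixels (> 0).
#' @param height Frame height in pixels (> 0).
#' @param fps Frames per second of the extracted sequence (> 0, default 6).
#' @return A `frame_geometry` object.
#' @export
#' @examples
#' frame_geometry(300, 300)
frame_geometry <- function(width, height, fps = 6) {
  stopifnot(is.numeric(width), is.numeric(height), is.numeric(fps),
            length(width) == 1, length(height) == 1, length(fps) == 1,
            width > 0, height > 0, fps > 0)
  structure(list(width = as.numeric(width), height = as.numeric(height),
                 fps = as.numeric(fps)),
            class = "frame_geometry")
}

#' Centroid of a detection geometry
#'
#' For an axis-aligned box, the center point. For a simple polygon, the
#' area-weighted centroid (shoelace formula). For a degenerate (zero-area)
#' polygon the vertex mean is returned. Self-intersecting polygons are
#' rejected: their signed-area centroid is not the centroid of any region.
#'
#' @param geometry Either a numeric vector `c(x_min, y_min, x_max, y_max)`
#'   (a box) or a two-column numeric matrix of polygon vertices in order
#'   (at least 3 rows).
#' @return Numeric vector `c(x, y)` in pixels.
#' @export
#' @examples
#' centroid(c(45, 45, 55, 55))               # box center (50, 50)
#' centroid(rbind(c(0, 0), c(3, 0), c(0, 3)))  # right triangle -> (1, 1)
centroid <- function(geometry) {
  if (is.matrix(geometry)) {
    poly <- geometry
    if (nrow(poly) < 3 || ncol(poly) != 2)
      kafr_stop("polygon needs >= 3 two-dimensional vertices", "kafr_geometry_error")
    if (!all(is.finite(poly)) || any(poly < 0))
      kafr_stop("polygon coordinates must be finite and >= 0", "kafr_geometry_error")
    if (.polygon_self_intersects(poly))
      kafr_stop("polygon is self-intersecting", "kafr_geometry_error")
    x <- poly[, 1]; y <- poly[, 2]
    xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
    cross <- x * yn - xn * y
    a2 <- sum(cross)                      # twice the signed area
    if (abs(a2) < 1e-12) {                # degenerate: collinear vertices
      return(c(x = mean(x), y = mean(y)))
    }
    cx <- sum((x + xn) * cross) / (3 * a2)
    cy <- sum((y + yn) * cross) / (3 * a2)
    return(c(x = cx, y = cy))
  }
  box <- as.numeric(geometry)
  .check_box(box)
  c(x = (box[1] + box[3]) / 2, y = (box[2] + box[4]) / 2)
}

.check_box <- function(box) {
  if (length(box) != 4 || !all(is.finite(box)))
    kafr_stop("box must be c(x_min, y_min, x_max, y_max), finite", "kafr_geometry_error")
  if (box[1] >= box[3] || box[2] >= box[4])
    kafr_stop("box must have x_min < x_max and y_min < y_max", "kafr_geometry_error")
  invisible(box)
}

# proper crossing test between segments p1-p2 and p3-p4 (shared endpoints
# of adjacent edges are skipped by the caller)
.segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

.polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  idx <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      # skip adjacent edges (share a vertex)
      if (abs(i - j) <= 1 || (i == 1 && j == n)) next
      if (.segments_cross(poly[idx[i, 1], ], poly[idx[i, 2], ],
                          poly[idx[j, 1], ], poly[idx[j, 2], ]))
        return(TRUE)
    }
  }
  FALSE
}

#' Intersection over union of two axis-aligned boxes
#'
#' @param a,b Numeric vectors `c(x_min, y_min, x_max, y_max)`.
#' @return IOU in `[0, 1]`; 0 for disjoint boxes.
#' @export
#' @examples
#' bbox_iou(c(0, 0, 2, 2), c(1, 1, 3, 3))  # 1/7
bbox_iou <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  .check_box(a); .check_box(b)
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / union
}

#' Assign a centroid to the left or right hand
#'
#' The frame is split by a vertical midline: a tool whose centroid lies on
#' the left half belongs to the left hand, otherwise to the right hand.
#' A centroid exactly on the midline is assigned right (a deterministic tie
#' rule). Centroids outside the frame bounds are clamped with a warning.
#'
#' @param c_point Numeric `c(x, y)` centroid in pixels.
#' @param fg A [frame_geometry()].
#' @return `"left"` or `"right"`.
#' @export
assign_hand <- function(c_point, fg) {
  stopifnot(inherits(fg, "frame_geometry"))
  x <- as.numeric(c_point)[1]
  if (!is.finite(x)) kafr_stop("centroid x must be finite", "kafr_geometry_error")
  if (x < 0 || x > fg$width) {
    warning("centroid outside frame bounds; clamping")
    x <- min(max(x, 0), fg$width)
  }
  if (x < fg$width / 2) "left" else "right"
}
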