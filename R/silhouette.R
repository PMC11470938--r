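#' Image parameters for silhouette rendering
#'
#' Geometry of the synthetic camera frames: a backlit fly appears as a dark
#' body ellipse with a dimmer (translucent) wing blob trailing behind it on a
#' bright background, mimicking the arena's IR backlight view. Intensities
#' are chosen so a two-threshold Otsu separates background / wings / body.
#'
#' Image convention: 1-based pixel coordinates, `x` = column (rightward),
#' `y` = row (downward); angles measured from +x toward +y (i.e. clockwise on
#' screen), so a heading of 0 points right and 90 points down the image.
#'
#' @param width,height frame size in pixels (default 1024, the camera
#'   resolution; 12 px/mm at the arena).
#' @param body_axes semi-major/semi-minor body axes, px (default 18 x 6,
#'   a ~3 mm fly at 12 px/mm).
#' @param wing_axes wing blob semi-axes, px.
#' @param wing_offset displacement of the wing-blob centre behind the body
#'   centre along -heading, px.
#' @param bg,wing,body grayscale intensities in `[0, 1]`.
#' @return list of class `image_params`.
#' @export
image_params <- function(width = 1024L, height = 1024L,
                         body_axes = c(18, 6), wing_axes = c(12, 7),
                         wing_offset = 16, bg = 0.9, wing = 0.55,
                         body = 0.12) {
  stopifnot(width > 0, height > 0, all(body_axes > 0), all(wing_axes > 0),
            bg > wing, wing > body, body >= 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 body_axes = body_axes, wing_axes = wing_axes,
                 wing_offset = wing_offset, bg = bg, wing = wing,
                 body = body),
            class = "image_params")
}

# paint an ellipse into `img` (matrix indexed [y, x]) over its bounding box
.paint_ellipse <- function(img, cx, cy, a, b, angle_deg, value) {
  th <- angle_deg * pi / 180
  ca <- cos(th); sa <- sin(th)
  r <- max(a, b)
  x0 <- max(1L, floor(cx - r)); x1 <- min(ncol(img), ceiling(cx + r))
  y0 <- max(1L, floor(cy - r)); y1 <- min(nrow(img), ceiling(cy + r))
  xs <- x0:x1; ys <- y0:y1
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  u <- dx * ca + dy * sa
  v <- -dx * sa + dy * ca
  inside <- (u / a)^2 + (v / b)^2 <= 1
  sub <- img[ys, xs, drop = FALSE]
  sub[inside] <- value
  img[ys, xs] <- sub
  img
}

#' Render a fly silhouette frame
#'
#' Draws the body ellipse at the given centre and heading and a wing blob
#' displaced behind the body (along -heading). See [image_params()] for the
#' image convention.
#'
#' @param cx,cy body centre, px.
#' @param heading_deg heading in image convention, degrees.
#' @param params an [image_params()].
#' @return grayscale matrix `height x width` in `[0, 1]` (row = y, col = x).
#'   Rendering is deterministic: identical poses give identical frames.
#' @export
render_silhouette <- function(cx, cy, heading_deg, params = image_params()) {
  stopifnot(inherits(params, "image_params"))
  a <- params$body_axes[1]; b <- params$body_axes[2]
  th <- heading_deg * pi / 180
  wx <- cx - params$wing_offset * cos(th)
  wy <- cy - params$wing_offset * sin(th)
  r_body <- max(a, b)
  r_wing <- max(params$wing_axes)
  if (cx - r_body < 1 || cx + r_body > params$width ||
      cy - r_body < 1 || cy + r_body > params$height ||
      wx - r_wing < 1 || wx + r_wing > params$width ||
      wy - r_wing < 1 || wy + r_wing > params$height)
    stop("fly (body or wings) partially outside the frame")
  img <- matrix(params$bg, nrow = params$height, ncol = params$width)
  img <- .paint_ellipse(img, wx, wy, params$wing_axes[1], params$wing_axes[2],
                        heading_deg, params$wing)
  .paint_ellipse(img, cx, cy, a, b, heading_deg, params$body)
}
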