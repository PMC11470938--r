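#' Two-threshold (three-class) Otsu thresholds
#'
#' Exhaustive maximisation of the between-class variance over all threshold
#' pairs on a binned histogram; the discrete analogue of Otsu's method for
#' three classes (here: body, translucent wings, background).
#'
#' @param values numeric pixel intensities.
#' @param n_bins histogram resolution (default 128).
#' @return numeric `c(t1, t2)` with `t1 < t2`: class 1 `<= t1`, class 2 in
#'   `(t1, t2]`, class 3 `> t2`.
#' @export
otsu_two_thresholds <- function(values, n_bins = 128L) {
  rng <- range(values)
  if (diff(rng) <= 0) stop("constant image: Otsu thresholds undefined")
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(values, br, rightmost.closed = TRUE,
                             all.inside = TRUE), n_bins)
  mids <- (br[-1] + br[-length(br)]) / 2
  W <- cumsum(h)
  M <- cumsum(h * mids)
  total_w <- W[n_bins]; total_m <- M[n_bins]
  best <- -Inf; t_best <- c(1L, 2L)
  for (i in seq_len(n_bins - 2L)) {
    w1 <- W[i]
    if (w1 == 0) next
    m1 <- M[i] / w1
    js <- (i + 1L):(n_bins - 1L)
    w2 <- W[js] - W[i]
    w3 <- total_w - W[js]
    ok <- w2 > 0 & w3 > 0
    if (!any(ok)) next
    m2 <- (M[js] - M[i]) / w2
    m3 <- (total_m - M[js]) / w3
    mg <- total_m / total_w
    sb <- w1 * (m1 - mg)^2 + w2 * (m2 - mg)^2 + w3 * (m3 - mg)^2
    sb[!ok] <- -Inf
    j <- which.max(sb)
    if (sb[j] > best) { best <- sb[j]; t_best <- c(i, js[j]) }
  }
  c(br[t_best[1] + 1L], br[t_best[2] + 1L])
}

#' Fit the body ellipse pose from a silhouette frame
#'
#' Thresholds the frame, labels connected components
#' (`EBImage::bwlabel`), takes the largest dark component (>= `min_px`
#' pixels), and fits an ellipse by image moments: the centroid and the
#' major-axis angle of the second-moment ellipse give the position and the
#' body-axis orientation (mod 180; the 180-degree ambiguity is resolved
#' separately by [resolve_heading()]).
#'
#' @param frame grayscale matrix (row = y, col = x), values in `[0, 1]`.
#' @param intensity_threshold pixels strictly below it are foreground (the
#'   online pipeline's fast body threshold; a required configuration value).
#' @param min_px minimum component size (default 20).
#' @return list of class `pose`: `centroid` (x, y in px), `body_axis_angle`
#'   (degrees mod 180, image convention), `heading` (NA until resolved),
#'   `ok` (logical), `flag` (`"ok"`, `"no_component"`, `"touching_border"`,
#'   `"degenerate_orientation"`), plus the component `bbox`
#'   (xmin, xmax, ymin, ymax) for downstream stages.
#' @export
fit_pose <- function(frame, intensity_threshold, min_px = 20L) {
  mask <- frame < intensity_threshold
  fail <- function(flag) list(centroid = c(NA_real_, NA_real_),
                              body_axis_angle = NA_real_,
                              heading = NA_real_, ok = FALSE, flag = flag,
                              bbox = NULL)
  rows_any <- which(rowSums(mask) > 0)
  cols_any <- which(colSums(mask) > 0)
  if (!length(rows_any)) return(structure(fail("no_component"),
                                          class = "pose"))
  # label only the foreground bounding box; full frames are mostly background
  ry <- range(rows_any); rx <- range(cols_any)
  sub <- mask[ry[1]:ry[2], rx[1]:rx[2], drop = FALSE]
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(sub * 1)))
  sizes <- tabulate(lab[lab > 0])
  big <- which.max(sizes)
  if (sizes[big] < min_px) return(structure(fail("no_component"),
                                            class = "pose"))
  idx <- which(lab == big, arr.ind = TRUE)  # [,1] = row = y, [,2] = col = x
  ys <- idx[, 1] + ry[1] - 1L; xs <- idx[, 2] + rx[1] - 1L
  if (min(xs) == 1 || max(xs) == ncol(frame) ||
      min(ys) == 1 || max(ys) == nrow(frame))
    return(structure(fail("touching_border"), class = "pose"))
  cx <- mean(xs); cy <- mean(ys)
  mu20 <- mean((xs - cx)^2); mu02 <- mean((ys - cy)^2)
  mu11 <- mean((xs - cx) * (ys - cy))
  # eigen spread of the second-moment matrix; near-equal -> no major axis
  tr <- mu20 + mu02
  det_ <- mu20 * mu02 - mu11^2
  disc <- sqrt(max(0, tr^2 / 4 - det_))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  out <- list(centroid = c(x = cx, y = cy), body_axis_angle = NA_real_,
              heading = NA_real_, ok = TRUE, flag = "ok",
              bbox = c(xmin = min(xs), xmax = max(xs),
                       ymin = min(ys), ymax = max(ys)))
  if (l2 <= 0 || l1 / l2 < 1.1) {
    out$flag <- "degenerate_orientation"
  } else {
    ang <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
    out$body_axis_angle <- ang %% 180
  }
  structure(out, class = "pose")
}

#' Resolve the 180-degree heading ambiguity from the wing shadow
#'
#' Computes two-threshold Otsu classes ([otsu_two_thresholds()]) on the fly's
#' expanded bounding box (so the bright background does not dominate the
#' histogram): the darkest class is the body, the intermediate class the
#' translucent wings. Since the wings trail the body, the heading is the one
#' of the two body-axis directions closer to the vector from the wing centre
#' of mass to the body centre of mass. A configuration flip is exposed for
#' rigs where the bright class ordering is inverted.
#'
#' @param frame grayscale matrix.
#' @param pose a successful [fit_pose()] result.
#' @param pad bounding-box expansion in px (default 40, enough to include
#'   the wing blob).
#' @param flip reverse the wing-to-body convention (default FALSE).
#' @param min_wing_px minimum wing-class size (default 10).
#' @return `pose` with `heading` set (degrees mod 360, image convention) and
#'   `flag = "ok"`, or flag `"heading_unresolved"` (body-axis angle kept).
#' @export
resolve_heading <- function(frame, pose, pad = 40L, flip = FALSE,
                            min_wing_px = 10L) {
  stopifnot(inherits(pose, "pose"))
  if (!pose$ok || is.na(pose$body_axis_angle)) return(pose)
  bb <- pose$bbox
  x0 <- max(1L, bb["xmin"] - pad); x1 <- min(ncol(frame), bb["xmax"] + pad)
  y0 <- max(1L, bb["ymin"] - pad); y1 <- min(nrow(frame), bb["ymax"] + pad)
  sub <- frame[y0:y1, x0:x1, drop = FALSE]
  th <- otsu_two_thresholds(as.numeric(sub))
  body_m <- sub <= th[1]
  wing_m <- sub > th[1] & sub <= th[2]
  if (sum(wing_m) < min_wing_px) {
    pose$flag <- "heading_unresolved"
    return(pose)
  }
  com <- function(m) {
    id <- which(m, arr.ind = TRUE)
    c(x = mean(id[, 2]) + x0 - 1, y = mean(id[, 1]) + y0 - 1)
  }
  cb <- com(body_m); cw <- com(wing_m)
  v <- cb - cw                       # wings trail: points toward the head
  if (flip) v <- -v
  ref <- atan2(v["y"], v["x"]) * 180 / pi
  cand <- c(pose$body_axis_angle, pose$body_axis_angle + 180)
  d <- abs(((cand - ref + 180) %% 360) - 180)
  pose$heading <- cand[which.min(d)] %% 360
  pose$flag <- "ok"
  pose
}

#' Track a stack of silhouette frames
#'
#' Runs [fit_pose()] and [resolve_heading()] over a list of frames and
#' returns a per-frame pose table with QC flags.
#'
#' @param frames list of grayscale matrices.
#' @param intensity_threshold see [fit_pose()].
#' @param ... passed to [resolve_heading()].
#' @return data.frame: `frame`, `x`, `y` (px), `body_axis_angle` (deg mod
#'   180), `heading` (deg mod 360), `ok`, `flag`.
#' @export
track_frames <- function(frames, intensity_threshold, ...) {
  rows <- lapply(seq_along(frames), function(i) {
    p <- fit_pose(frames[[i]], intensity_threshold)
    if (p$ok && !is.na(p$body_axis_angle))
      p <- resolve_heading(frames[[i]], p, ...)
    data.frame(frame = i, x = p$centroid[1], y = p$centroid[2],
               body_axis_angle = p$body_axis_angle, heading = p$heading,
               ok = p$ok && p$flag == "ok", flag = p$flag)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Convert tracked pixel poses to arena coordinates
#'
#' Image coordinates are y-down; the arena frame is y-up with CCW-positive
#' angles and millimetre units (12 px/mm). The conversion mirrors y about
#' the image centre and negates angles.
#'
#' @param poses data.frame from [track_frames()].
#' @param px_per_mm pixel pitch (default 12).
#' @param width,height frame size in px (default 1024).
#' @return data.frame with `x_mm`, `y_mm` (arena frame, origin at the image
#'   centre) and `heading_arena` (deg, CCW-positive).
#' @export
pose_to_arena <- function(poses, px_per_mm = 12, width = 1024L,
                          height = 1024L) {
  cx <- (width + 1) / 2; cy <- (height + 1) / 2
  poses$x_mm <- (poses$x - cx) / px_per_mm
  poses$y_mm <- (cy - poses$y) / px_per_mm
  poses$heading_arena <- (-poses$heading) %% 360
  poses
}
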