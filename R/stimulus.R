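#' Pinwheel grating pattern
#'
#' Describes the radial grating used on the arena roof: a pinwheel whose
#' intensity varies with pinwheel angle, either sinusoidally or as a square
#' wave.
#'
#' @param max_intensity,min_intensity luminances (arbitrary units, >= 0),
#'   `max_intensity >= min_intensity`.
#' @param spatial_period degrees of pinwheel angle per cycle (> 0).
#' @param profile `"sinusoidal"` (default) or `"square"`.
#' @return object of class `grating_pattern`.
#' @export
grating_pattern <- function(max_intensity, min_intensity, spatial_period = 30,
                            profile = c("sinusoidal", "square")) {
  profile <- match.arg(profile)
  stopifnot(is.numeric(max_intensity), is.numeric(min_intensity),
            max_intensity >= 0, min_intensity >= 0,
            max_intensity >= min_intensity, spatial_period > 0)
  structure(list(max_intensity = max_intensity, min_intensity = min_intensity,
                 spatial_period = spatial_period, profile = profile),
            class = "grating_pattern")
}

#' Michelson contrast of a grating pattern
#'
#' `(max - min) / (max + min)`, in `[0, 1]`. Both intensities zero leaves the
#' contrast undefined and is an error rather than silently 0.
#'
#' @param pattern a [grating_pattern()].
#' @return contrast, dimensionless scalar in `[0, 1]`.
#' @export
michelson_contrast <- function(pattern) {
  stopifnot(inherits(pattern, "grating_pattern"))
  s <- pattern$max_intensity + pattern$min_intensity
  if (s <= 0) stop("undefined contrast: both intensities are zero")
  (pattern$max_intensity - pattern$min_intensity) / s
}

#' Stimulus condition descriptor
#'
#' A trial's pinwheel stimulus: full-field rotation, unilateral front-to-back
#' or back-to-front motion (one pinwheel half rotates, the other stays
#' static, split along the fly's body axis), or a static pattern.
#'
#' Sign convention used throughout the package: arena angles are CCW-positive
#' (y-up); `"CW"` means the pattern angle decreases over time.
#'
#' @param kind one of `"full_field"`, `"unilateral_FtB"`, `"unilateral_BtF"`,
#'   `"static"`.
#' @param rotation_dir `"CW"`, `"CCW"`, or `"none"` (required for
#'   `kind = "static"`).
#' @param pattern a [grating_pattern()].
#' @param stimulated_eye for unilateral kinds, which eye sees motion
#'   (`"left"` or `"right"`).
#' @param pinwheel_diameter mm (default 45, where the optomotor response
#'   saturates).
#' @param rotation_speed deg/s of pattern rotation.
#' @param static_duration,motion_duration seconds (defaults 5 and 5).
#' @param segment_split_angle degrees, midline of the two pinwheel segments
#'   relative to the fly's body axis (default 0: split on the body axis).
#' @return object of class `stimulus_condition`.
#' @export
stimulus_condition <- function(kind = c("full_field", "unilateral_FtB",
                                        "unilateral_BtF", "static"),
                               rotation_dir = c("CW", "CCW", "none"),
                               pattern = grating_pattern(1, 0),
                               stimulated_eye = c("left", "right"),
                               pinwheel_diameter = 45, rotation_speed = 180,
                               static_duration = 5, motion_duration = 5,
                               segment_split_angle = 0) {
  kind <- match.arg(kind)
  dir_given <- !missing(rotation_dir)
  rotation_dir <- match.arg(rotation_dir)
  stimulated_eye <- match.arg(stimulated_eye)
  stopifnot(static_duration > 0, motion_duration > 0, pinwheel_diameter > 0)
  if (kind == "static") {
    if (dir_given && rotation_dir != "none")
      stop("a static condition must have rotation_dir = 'none'")
    rotation_dir <- "none"
  } else if (kind %in% c("unilateral_FtB", "unilateral_BtF")) {
    # the rotation direction of the moving half follows from the motion class
    # and the stimulated eye under the CCW-positive convention
    derived <- if (xor(kind == "unilateral_FtB", stimulated_eye == "right"))
      "CCW" else "CW"
    if (dir_given && rotation_dir != derived)
      stop("rotation_dir '", rotation_dir, "' is inconsistent with ", kind,
           " over the ", stimulated_eye, " eye (expected ", derived, ")")
    rotation_dir <- derived
  } else if (rotation_dir == "none") {
    stop("a moving condition needs rotation_dir 'CW' or 'CCW'")
  }
  structure(list(kind = kind, rotation_dir = rotation_dir, pattern = pattern,
                 stimulated_eye = stimulated_eye,
                 pinwheel_diameter = pinwheel_diameter,
                 rotation_speed = rotation_speed,
                 static_duration = static_duration,
                 motion_duration = motion_duration,
                 segment_split_angle = segment_split_angle),
            class = "stimulus_condition")
}

#' Closed-loop stimulus anchor angle
#'
#' The pinwheel is locked to the fly's body axis with a fixed update delay
#' (3 frames, <48 ms, in the experiment): the anchor at frame `t` is the body
#' angle at frame `t - delay_frames`. The first `delay_frames` entries hold the
#' initial angle.
#'
#' @param body_angle_history body angle per frame, degrees.
#' @param delay_frames non-negative integer update delay (default 3).
#' @return stimulus anchor angle per frame, degrees.
#' @export
closed_loop_angle <- function(body_angle_history, delay_frames = 3L) {
  stopifnot(length(body_angle_history) >= 1, delay_frames >= 0)
  n <- length(body_angle_history)
  d <- min(as.integer(delay_frames), n)
  if (d == 0L) return(body_angle_history)
  c(rep(body_angle_history[1L], d), body_angle_history[seq_len(n - d)])
}

# stimulus rotation sign under the package convention: CCW-positive
stimulus_sign <- function(rotation_dir) {
  switch(rotation_dir, CCW = 1, CW = -1, none = 0,
         stop("unknown rotation_dir"))
}

#' Local motion class experienced by one eye
#'
#' Decomposes a rotating pinwheel about the body axis: under the CCW-positive
#' convention, CCW rotation carries pattern in front of the fly toward its
#' left, i.e. front-to-back over the left eye and back-to-front over the
#' right eye; CW is the mirror image. Unilateral conditions move only over the
#' stimulated eye; static conditions move over neither.
#'
#' @param condition a [stimulus_condition()].
#' @param eye `"left"` or `"right"`.
#' @return `"FtB"`, `"BtF"`, or `"none"`.
#' @export
local_motion_direction <- function(condition, eye = c("left", "right")) {
  stopifnot(inherits(condition, "stimulus_condition"))
  eye <- match.arg(eye)
  if (condition$kind == "static") return("none")
  ftb_eye <- if (condition$rotation_dir == "CCW") "left" else "right"
  if (condition$kind == "full_field")
    return(if (eye == ftb_eye) "FtB" else "BtF")
  if (eye != condition$stimulated_eye) return("none")
  if (condition$kind == "unilateral_FtB") "FtB" else "BtF"
}

#' Serialize stimulus conditions to JSON
#'
#' @param conditions a list of [stimulus_condition()] objects.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_conditions_json <- function(conditions, path) {
  if (inherits(conditions, "stimulus_condition")) conditions <- list(conditions)
  payload <- lapply(conditions, function(cd) {
    c(unclass(cd)[setdiff(names(cd), "pattern")],
      list(pattern = unclass(cd$pattern),
           contrast = michelson_contrast(cd$pattern)))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
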