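## Geometric transforms and the training-time augmentation policy.

#' Affine transform of an image about its center
#'
#' Applies, in order: horizontal/vertical flip, rotation, zoom, then shift.
#' Output pixels are bilinearly sampled from the inverse mapping; pixels
#' that fall outside the source frame are filled with `fill` (default 0,
#' matching the black background of radiographs). The rotation convention:
#' a point at (row, col) relative to the center is sampled from
#' `R(angle) %*% (row, col)` in the source, with `R` the standard 2D
#' rotation matrix acting on (row, col).
#'
#' @param img numeric matrix.
#' @param angle rotation in degrees.
#' @param zoom scale factor (> 0); 1 is identity, > 1 magnifies.
#' @param shift length-2 numeric, (row, col) translation in pixels.
#' @param hflip,vflip mirror about the vertical / horizontal axis.
#' @param fill out-of-frame fill value.
#' @return Transformed matrix, same shape, values clipped to `[0, 1]` when
#'   the input lies in `[0, 1]`.
#' @export
affine_transform <- function(img, angle = 0, zoom = 1, shift = c(0, 0),
                             hflip = FALSE, vflip = FALSE, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  if (zoom <= 0) abort_config("`zoom` must be positive")
  ctr_r <- (nr + 1) / 2; ctr_c <- (nc + 1) / 2
  out_r <- rep(seq_len(nr), times = nc) - ctr_r
  out_c <- rep(seq_len(nc), each = nr) - ctr_c
  ## invert shift, then zoom, then rotation
  pr <- (out_r - shift[1]) / zoom
  pc <- (out_c - shift[2]) / zoom
  th <- angle * pi / 180
  src_r <- cos(th) * pr - sin(th) * pc
  src_c <- sin(th) * pr + cos(th) * pc
  ## invert the flips (applied first in the forward direction)
  if (hflip) src_c <- -src_c
  if (vflip) src_r <- -src_r
  v <- bilinear_sample(img, src_r + ctr_r, src_c + ctr_c, oob = "fill", fill = fill)
  out <- matrix(v, nr, nc)
  if (min(img) >= 0 && max(img) <= 1) out <- clip01(out)
  out
}

#' Training-time augmentation policy
#'
#' Random horizontal flips, rotations, zooms and shifts, the canonical
#' policy for training-set augmentation. Brightness jitter is available but
#' off by default (it belongs to an alternative regularization recipe, not
#' the canonical policy).
#'
#' @param rotation_limit max |rotation| in degrees (default 30).
#' @param zoom_limit max zoom deviation as a proportion (default 0.20).
#' @param shift_limit max shift as a proportion of the side (default 0.20).
#' @param horizontal_flip allow flips with probability 0.5 (default `TRUE`).
#' @param brightness_limit max multiplicative brightness jitter (default 0,
#'   i.e. disabled).
#' @param seed integer seed for the policy's draw stream.
#' @return An `augmentation_policy` list.
#' @export
augmentation_policy <- function(rotation_limit = 30, zoom_limit = 0.20,
                                shift_limit = 0.20, horizontal_flip = TRUE,
                                brightness_limit = 0, seed = 1L) {
  assert_number(rotation_limit, "rotation_limit", min = 0)
  assert_number(zoom_limit, "zoom_limit", min = 0, max = 0.99)
  assert_number(shift_limit, "shift_limit", min = 0)
  assert_flag(horizontal_flip, "horizontal_flip")
  assert_number(brightness_limit, "brightness_limit", min = 0, max = 1)
  structure(
    list(rotation_limit = rotation_limit, zoom_limit = zoom_limit,
         shift_limit = shift_limit, horizontal_flip = horizontal_flip,
         brightness_limit = brightness_limit, seed = seed),
    class = "augmentation_policy"
  )
}

#' Draw one random augmentation of a sample
#'
#' Rotation angle ~ U(-limit, limit), zoom ~ U(1 - z, 1 + z), shifts
#' ~ U(-s, s) times the image side, flip with probability 0.5. Out-of-frame
#' pixels are filled with 0. Pass `draw` to force a specific transform
#' (fields `angle`, `zoom`, `shift`, `hflip`, `brightness`).
#'
#' @param sample a [radiograph_sample()].
#' @param policy an [augmentation_policy()].
#' @param draw optional list of forced draw values (bypasses the RNG).
#' @return The augmented sample.
#' @export
augment_sample <- function(sample, policy, draw = NULL) {
  if (is.null(draw)) {
    draw <- list(
      angle = runif(1, -policy$rotation_limit, policy$rotation_limit),
      zoom = runif(1, 1 - policy$zoom_limit, 1 + policy$zoom_limit),
      shift = runif(2, -policy$shift_limit, policy$shift_limit) *
        c(nrow(sample$pixels), ncol(sample$pixels)),
      hflip = policy$horizontal_flip && runif(1) < 0.5,
      brightness = if (policy$brightness_limit > 0)
        1 + runif(1, -policy$brightness_limit, policy$brightness_limit) else 1
    )
  }
  px <- affine_transform(sample$pixels, angle = draw$angle %||% 0,
                         zoom = draw$zoom %||% 1,
                         shift = draw$shift %||% c(0, 0),
                         hflip = isTRUE(draw$hflip))
  b <- draw$brightness %||% 1
  if (b != 1) px <- clip01(px * b)
  out <- sample
  out$pixels <- px
  out
}
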