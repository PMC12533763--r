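#' Region-of-interest layout for a four-image array
#'
#' Builds the screen geometry for one trial's image array: four 300 x 300 px
#' images, one per screen quadrant, each surrounded by a 50 px margin so that
#' near-misses still count as looks to the image. A gaze sample is assigned
#' to an image when it falls inside the padded box (image box expanded by
#' `pad` on every side, clamped to the screen).
#'
#' The default placement insets the images from the quadrant centers so that
#' the padded boxes remain pairwise disjoint and on-screen; overlapping
#' regions of interest would make role assignment ambiguous. `rotation_id`
#' selects one of the four counterbalanced placements by cyclically shifting
#' which physical box corresponds to quadrants q1..q4.
#'
#' @param rotation_id Integer in 1..4 selecting the counterbalanced placement
#'   (default 1).
#' @param screen_w,screen_h Screen resolution in px (default 1024 x 768).
#' @param image_w,image_h Image size in px (default 300 x 300).
#' @param pad Margin added on every side of each image, in px (default 50).
#' @param centers Optional 4 x 2 matrix of image center coordinates
#'   (rows = quadrants q1 top-left, q2 top-right, q3 bottom-left,
#'   q4 bottom-right). Defaults to an inset placement.
#'
#' @return An object of class `roi_layout` with the padded ROI boxes
#'   (`boxes`: one row per quadrant with closed edges `x0 <= x <= x1`,
#'   `y0 <= y <= y1`) and the unpadded image boxes (`image_boxes`).
#' @export
roi_layout <- function(rotation_id = 1L, screen_w = 1024, screen_h = 768,
                       image_w = 300, image_h = 300, pad = 50,
                       centers = NULL) {
  if (!rotation_id %in% 1:4) {
    stop("`rotation_id` must be an integer in 1..4", call. = FALSE)
  }
  if (is.null(centers)) {
    # inset placement: columns at 212/812, rows at 170/598 keep the padded
    # 400x400 boxes disjoint and on a 1024x768 screen
    cx <- c(screen_w * 212 / 1024, screen_w * 812 / 1024)
    cy <- c(screen_h * 170 / 768, screen_h * 598 / 768)
    centers <- rbind(
      c(cx[1], cy[1]), c(cx[2], cy[1]),
      c(cx[1], cy[2]), c(cx[2], cy[2])
    )
  }
  centers <- as.matrix(centers)
  if (!identical(dim(centers), c(4L, 2L))) {
    stop("`centers` must be a 4 x 2 matrix (one row per quadrant)", call. = FALSE)
  }
  rot <- ((seq_len(4) - 1 + (rotation_id - 1)) %% 4) + 1
  centers <- centers[rot, , drop = FALSE]

  img <- data.frame(
    quadrant = paste0("q", 1:4),
    x0 = centers[, 1] - image_w / 2, x1 = centers[, 1] + image_w / 2,
    y0 = centers[, 2] - image_h / 2, y1 = centers[, 2] + image_h / 2
  )
  pb <- transform(
    img,
    x0 = pmax(x0 - pad, 0), x1 = pmin(x1 + pad, screen_w),
    y0 = pmax(y0 - pad, 0), y1 = pmin(y1 + pad, screen_h)
  )
  for (i in 1:3) {
    for (j in (i + 1):4) {
      overlap <- pb$x0[i] <= pb$x1[j] && pb$x0[j] <= pb$x1[i] &&
        pb$y0[i] <= pb$y1[j] && pb$y0[j] <= pb$y1[i]
      if (overlap) {
        stop(
          "padded ROI boxes for ", pb$quadrant[i], " and ", pb$quadrant[j],
          " overlap; adjust `centers`, `pad`, or image size",
          call. = FALSE
        )
      }
    }
  }
  structure(
    list(
      screen_w = screen_w, screen_h = screen_h,
      image_w = image_w, image_h = image_h, pad = pad,
      rotation_id = as.integer(rotation_id),
      boxes = pb, image_boxes = img
    ),
    class = "roi_layout"
  )
}

#' @export
print.roi_layout <- function(x, ...) {
  cat(sprintf(
    "<roi_layout> %g x %g screen, %g x %g images + %g px pad, rotation %d\n",
    x$screen_w, x$screen_h, x$image_w, x$image_h, x$pad, x$rotation_id
  ))
  print(x$boxes, row.names = FALSE)
  invisible(x)
}

# Vectorized quadrant hit test: returns integer quadrant index or NA.
# Containment is closed on all edges; boxes are disjoint so at most one hits.
roi_quadrant <- function(x, y, layout) {
  b <- layout$boxes
  out <- rep(NA_integer_, length(x))
  for (k in 1:4) {
    hit <- x >= b$x0[k] & x <= b$x1[k] & y >= b$y0[k] & y <= b$y1[k]
    hit[is.na(hit)] <- FALSE
    out[hit] <- k
  }
  out
}

#' Assign gaze coordinates to image roles
#'
#' Maps gaze sample coordinates to the role of the image whose padded region
#' of interest contains them. Containment is closed on all edges (a sample
#' exactly 50 px left of an image's left edge belongs to that image); padded
#' boxes are disjoint by construction so no point can match two images.
#'
#' @param x,y Numeric vectors of gaze coordinates in px.
#' @param layout A `roi_layout`.
#' @param trial_roles Named character vector mapping quadrants to roles, e.g.
#'   `c(q1 = "target", q2 = "cu_target", q3 = "distractor1", q4 = "distractor2")`.
#' @param valid Optional logical vector; samples flagged invalid (blinks,
#'   track loss) are returned as `NA` regardless of position.
#' @return Character vector of roles, `NA` where the sample hits no ROI or is
#'   invalid.
#' @export
assign_roi <- function(x, y, layout, trial_roles, valid = NULL) {
  stopifnot(inherits(layout, "roi_layout"))
  qs <- paste0("q", 1:4)
  if (!all(qs %in% names(trial_roles))) {
    stop("`trial_roles` must name all four quadrants q1..q4", call. = FALSE)
  }
  roles <- as.character(trial_roles[qs])
  if (anyDuplicated(roles)) {
    stop("`trial_roles` must map the four quadrants to distinct roles", call. = FALSE)
  }
  idx <- roi_quadrant(x, y, layout)
  out <- roles[idx]
  if (!is.null(valid)) {
    out[!valid] <- NA_character_
  }
  out
}
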