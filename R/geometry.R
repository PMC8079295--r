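#' Shuttle-box arena geometry
#'
#' Describes the two-compartment choice chamber: two circular compartments
#' joined by a rectangular passage, with one rectangular shelter zone (the
#' footprint of a PVC refuge tube, dilated by a margin) per compartment.
#'
#' The coordinate convention places the origin at the arena centroid with the
#' x-axis along the compartment-passage-compartment line, so the left
#' compartment centre sits at negative x and the right at positive x. The
#' passage rectangle is centred on the origin.
#'
#' @param compartment_diameter Diameter of each circular compartment (cm).
#' @param passage_width Width of the connecting passage (cm, y extent).
#' @param passage_length Length of the connecting passage (cm, x extent).
#' @param shelter_length,shelter_width Footprint of the shelter tube (cm).
#' @param shelter_margin Dilation (cm) added around the tube footprint when
#'   scoring "in shelter"; the behavioural definition of shelter occupancy is
#'   a geometric choice, not a physical property of the tube.
#' @param shelter_offset Offset (cm, `c(dx, dy)`) of each shelter-zone centre
#'   from its compartment centre; the default places the tube halfway between
#'   centre and wall, clear of the compartment centre.
#'
#' @return An object of class `arena_geometry`: a list with the compartment
#'   radius and centres, the passage rectangle and the two shelter rectangles
#'   (each `c(xmin, xmax, ymin, ymax)`).
#' @examples
#' geom <- arena_geometry()
#' geom$compartment_centers
#' @export
arena_geometry <- function(compartment_diameter = 50,
                           passage_width = 8.5,
                           passage_length = 14,
                           shelter_length = 15,
                           shelter_width = 2.6,
                           shelter_margin = 1,
                           shelter_offset = NULL) {
  if (compartment_diameter <= 0 || passage_width <= 0 || passage_length <= 0) {
    stop("arena dimensions must be positive", call. = FALSE)
  }
  r <- compartment_diameter / 2
  # circles tangent to the passage ends
  cx <- passage_length / 2 + r
  centers <- list(left = c(-cx, 0), right = c(cx, 0))
  sl <- shelter_length + 2 * shelter_margin
  sw <- shelter_width + 2 * shelter_margin
  if (sl > compartment_diameter || sw > compartment_diameter) {
    stop("shelter zone does not fit inside a compartment", call. = FALSE)
  }
  if (is.null(shelter_offset)) shelter_offset <- c(0, -r / 2)
  shelter <- function(center) {
    center <- center + shelter_offset
    c(xmin = center[1] - sl / 2, xmax = center[1] + sl / 2,
      ymin = center[2] - sw / 2, ymax = center[2] + sw / 2)
  }
  out <- structure(list(
    compartment_radius = r,
    compartment_diameter = compartment_diameter,
    passage_width = passage_width,
    passage_length = passage_length,
    compartment_centers = centers,
    passage_rect = c(xmin = -passage_length / 2, xmax = passage_length / 2,
                     ymin = -passage_width / 2, ymax = passage_width / 2),
    shelter_zones = list(left = shelter(centers$left),
                         right = shelter(centers$right))
  ), class = "arena_geometry")
  # shelter corners must lie inside the compartment circle
  for (side in c("left", "right")) {
    z <- out$shelter_zones[[side]]
    cc <- centers[[side]]
    corners <- expand.grid(x = z[c("xmin", "xmax")], y = z[c("ymin", "ymax")])
    d <- sqrt((corners$x - cc[1])^2 + (corners$y - cc[2])^2)
    if (any(d > r + 1e-9)) {
      stop("shelter zone extends outside its compartment", call. = FALSE)
    }
  }
  out
}

#' @export
print.arena_geometry <- function(x, ...) {
  cat("<arena_geometry>\n")
  cat(sprintf("  compartments: 2 circles, diameter %.1f cm, centers x = %s %.1f cm\n",
              x$compartment_diameter, "±", abs(x$compartment_centers$right[1])))
  cat(sprintf("  passage: %.1f x %.1f cm (L x W)\n", x$passage_length, x$passage_width))
  cat(sprintf("  shelter zones: %.1f x %.1f cm per compartment\n",
              diff(x$shelter_zones$left[c("xmin", "xmax")]),
              diff(x$shelter_zones$left[c("ymin", "ymax")])))
  invisible(x)
}

in_rect <- function(x, y, rect) {
  x >= rect["xmin"] & x <= rect["xmax"] & y >= rect["ymin"] & y <= rect["ymax"]
}

#' Assign arena zones to points
#'
#' Classifies each point as `left`, `right` or `passage` and flags shelter
#' occupancy. Boundary ties go to the passage: a point inside the passage
#' rectangle is `passage` even where the rectangle touches a compartment
#' circle, which makes compartment changes well defined.
#'
#' @param x,y Coordinates (cm), vectorised.
#' @param geometry An [arena_geometry()].
#' @return A tibble with columns `zone` (factor: left/right/passage) and
#'   `in_shelter` (logical).
#' @examples
#' geom <- arena_geometry()
#' assign_zone(geom$compartment_centers$left[1], 0, geom)
#' @export
assign_zone <- function(x, y, geometry) {
  stopifnot(inherits(geometry, "arena_geometry"), length(x) == length(y))
  r <- geometry$compartment_radius
  cl <- geometry$compartment_centers$left
  cr <- geometry$compartment_centers$right
  in_pass <- in_rect(x, y, geometry$passage_rect)
  in_left <- (x - cl[1])^2 + (y - cl[2])^2 <= r^2
  in_right <- (x - cr[1])^2 + (y - cr[2])^2 <= r^2
  zone <- rep(NA_character_, length(x))
  zone[in_right] <- "right"
  zone[in_left] <- "left"
  zone[in_pass] <- "passage"   # ties resolved to passage
  if (anyNA(zone)) {
    i <- which(is.na(zone))[1]
    stop(sprintf("point (%.2f, %.2f) is outside the arena", x[i], y[i]),
         call. = FALSE)
  }
  in_shelter <- (zone == "left" & in_rect(x, y, geometry$shelter_zones$left)) |
    (zone == "right" & in_rect(x, y, geometry$shelter_zones$right))
  tibble::tibble(zone = factor(zone, levels = c("left", "right", "passage")),
                 in_shelter = in_shelter)
}

#' Test whether points lie inside the arena footprint
#'
#' @inheritParams assign_zone
#' @return Logical vector.
#' @export
in_arena <- function(x, y, geometry) {
  r <- geometry$compartment_radius
  cl <- geometry$compartment_centers$left
  cr <- geometry$compartment_centers$right
  in_rect(x, y, geometry$passage_rect) |
    (x - cl[1])^2 + (y - cl[2])^2 <= r^2 |
    (x - cr[1])^2 + (y - cr[2])^2 <= r^2
}
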