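#' Three-chamber arena layout
#'
#' Describes the geometry of a three-chamber sociability arena: a rectangular
#' floor split into three equal-width chambers along the x axis, with one
#' stimulus enclosure centered in each outer chamber. A circular "proximity
#' zone" is drawn around each enclosure; its diameter defaults to the
#' enclosure diameter plus 5 cm, where the enclosure diameter of a
#' rectangular enclosure is taken as its longest side.
#'
#' @param arena_w,arena_h Arena floor dimensions in cm.
#' @param enclosure_w,enclosure_h Enclosure footprint in cm.
#' @param zone_diameter Proximity-zone diameter in cm. Default
#'   `max(enclosure_w, enclosure_h) + 5`.
#' @param social_side Which outer chamber holds the social stimulus
#'   (`"left"` or `"right"`); the opposite chamber holds the empty
#'   enclosure (object). Exposed for counterbalancing.
#'
#' @return An object of class `arena_layout`: a list with the arena
#'   dimensions, the three chamber x-intervals, the named enclosure centers
#'   (`social`, `object`), the enclosure dimensions and the zone diameter.
#' @export
#' @examples
#' layout <- arena_layout()
#' layout$zone_diameter  # 21 cm
arena_layout <- function(arena_w = 60, arena_h = 40,
                         enclosure_w = 16, enclosure_h = 9,
                         zone_diameter = NULL,
                         social_side = c("left", "right")) {
  social_side <- match.arg(social_side)
  if (arena_w <= 0 || arena_h <= 0)
    stop_socphys("layout_error", "arena dimensions must be positive")
  if (is.null(zone_diameter))
    zone_diameter <- max(enclosure_w, enclosure_h) + 5
  if (zone_diameter <= max(enclosure_w, enclosure_h))
    stop_socphys("layout_error",
                 "zone_diameter must exceed the largest enclosure dimension")
  cw <- arena_w / 3
  chambers <- list(left   = c(0, cw),
                   center = c(cw, 2 * cw),
                   right  = c(2 * cw, arena_w))
  left_c  <- c(cw / 2, arena_h / 2)
  right_c <- c(arena_w - cw / 2, arena_h / 2)
  centers <- if (social_side == "left") {
    list(social = left_c, object = right_c)
  } else {
    list(social = right_c, object = left_c)
  }
  for (p in centers) {
    if (p[1] < 0 || p[1] > arena_w || p[2] < 0 || p[2] > arena_h)
      stop_socphys("layout_error", "enclosure center outside arena")
  }
  structure(
    list(arena_w = arena_w, arena_h = arena_h,
         chamber_bounds = chambers,
         enclosure_centers = centers,
         enclosure_dims = c(w = enclosure_w, h = enclosure_h),
         zone_diameter = zone_diameter,
         social_side = social_side),
    class = "arena_layout"
  )
}

#' @export
print.arena_layout <- function(x, ...) {
  cat(sprintf("<arena_layout> %g x %g cm, 3 chambers of %g cm\n",
              x$arena_w, x$arena_h, x$arena_w / 3))
  cat(sprintf("  social enclosure at (%g, %g) [%s side], object at (%g, %g)\n",
              x$enclosure_centers$social[1], x$enclosure_centers$social[2],
              x$social_side,
              x$enclosure_centers$object[1], x$enclosure_centers$object[2]))
  cat(sprintf("  proximity zone diameter %g cm\n", x$zone_diameter))
  invisible(x)
}

zone_radius <- function(layout) layout$zone_diameter / 2

# closed-disc membership: points on the circle count as inside
in_zone <- function(x, y, layout, zone) {
  ctr <- layout$enclosure_centers[[zone]]
  if (is.null(ctr)) stop_socphys("layout_error", paste("unknown zone:", zone))
  (x - ctr[1])^2 + (y - ctr[2])^2 <= zone_radius(layout)^2
}
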