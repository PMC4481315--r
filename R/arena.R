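#' Arena geometry
#'
#' Planform (top-view) geometry of the flight arena, in meters. The frame
#' convention used everywhere in the package: x runs along the long axis
#' with the perch near x = 0, y across the width. A yaw of 0 deg faces +x
#' (away from the perch along the long axis), 180 deg faces the perch, and
#' positive yaw is a leftward (counter-clockwise, towards +y) rotation.
#'
#' The default reproduces the study arena: 0.6 m x 1.0 m planform, a
#' 0.213 m wide swinging perch hung 0.115 m from one side wall, a white
#' side wall carrying a 0.25 m wide gray panel at its center, and
#' high-contrast corners where the white wall meets the dark end walls.
#'
#' @param width,length arena planform size in meters (width across y,
#'   length along x).
#' @param perch_x fore-aft position of the perch line, meters from the
#'   x = 0 wall.
#' @param perch_width perch width, meters.
#' @param perch_wall_gap distance of the near perch edge from the y = 0
#'   side wall, meters.
#' @param gray_square_width width of the gray wall panel, meters; the panel
#'   is centered on the white side wall at y = `width`.
#' @return object of class `arena_geometry`: named planform feature points
#'   plus the arena bounds.
#' @export
arena_geometry <- function(width = 0.6, length = 1.0,
                           perch_x = 0.1, perch_width = 0.213,
                           perch_wall_gap = 0.115,
                           gray_square_width = 0.25) {
  stopifnot(width > 0, length > 0, perch_width > 0,
            perch_wall_gap + perch_width <= width)
  y_lo <- perch_wall_gap
  y_hi <- perch_wall_gap + perch_width
  features <- rbind(
    corner_white_dark_back  = c(0, width),
    corner_white_dark_front = c(length, width),
    gray_square_left        = c(length / 2 - gray_square_width / 2, width),
    gray_square_right       = c(length / 2 + gray_square_width / 2, width),
    perch_center            = c(perch_x, (y_lo + y_hi) / 2),
    perch_left_edge         = c(perch_x, y_lo),
    perch_right_edge        = c(perch_x, y_hi)
  )
  colnames(features) <- c("x", "y")
  if (any(features[, 1] < 0 | features[, 1] > length |
          features[, 2] < 0 | features[, 2] > width)) {
    stop("arena features must lie inside the arena bounds")
  }
  structure(list(width = width, length = length,
                 perch_x = perch_x, perch_width = perch_width,
                 perch_wall_gap = perch_wall_gap,
                 gray_square_width = gray_square_width,
                 features = features),
            class = "arena_geometry")
}

#' Read / write arena geometry as YAML
#'
#' The config file stores the constructor arguments (schema version 1), so
#' a round trip reproduces the geometry exactly.
#'
#' @param path file path of a YAML config.
#' @param geometry an `arena_geometry` object.
#' @return `read_arena()` returns an `arena_geometry`; `write_arena()`
#'   returns `path` invisibly.
#' @export
read_arena <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$schema) || cfg$schema != "arena/1") {
    stop("unrecognized arena config schema: ", cfg$schema)
  }
  arena_geometry(width = cfg$width, length = cfg$length,
                 perch_x = cfg$perch_x, perch_width = cfg$perch_width,
                 perch_wall_gap = cfg$perch_wall_gap,
                 gray_square_width = cfg$gray_square_width)
}

#' @rdname read_arena
#' @export
write_arena <- function(geometry, path) {
  stopifnot(inherits(geometry, "arena_geometry"))
  yaml::write_yaml(c(list(schema = "arena/1"),
                     geometry[c("width", "length", "perch_x", "perch_width",
                                "perch_wall_gap", "gray_square_width")]),
                   path)
  invisible(path)
}
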