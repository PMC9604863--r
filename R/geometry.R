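# Maze geometry: a regular-pentagon hub with five radiating alleys.

#' Construct a star-maze geometry
#'
#' Builds the five-alley star maze used for trajectory scoring: five
#' corridors radiate from the angles of a regular pentagon, numbered 1..5
#' counterclockwise with the alley-1 axis pointing along +90 degrees.
#' Distances are in (virtual) meters with the maze center at the origin.
#'
#' The default dimensions are calibrated so that the direct route between
#' two alley reward positions through the center — the route scored as
#' "ideal" (e.g. alley 1 to alley 3) — is exactly 246 m long, the
#' theoretical best total path length against which distance error is
#' expressed. The calibration constants are carried in the returned object
#' so that any emitted configuration is self-describing.
#'
#' @param pentagon_circumradius Circumradius of the central pentagon (m).
#' @param alley_length Corridor length beyond the pentagon boundary (m).
#' @param alley_width Corridor width (m); must be smaller than a pentagon
#'   side so corridors do not overlap.
#' @param treasure_offset Depth of the reward (and of the start position)
#'   into an alley, measured past the pentagon boundary (m).
#' @param entry_depth Depth past the pentagon boundary a point must
#'   strictly exceed to count as "inside" an alley (m).
#' @param exit_hysteresis Depth drop below `entry_depth` required to count
#'   as having left an alley again (m); suppresses chattering at the
#'   boundary when counting alley-entry events.
#' @param capture_radius Radius around the reward position within which the
#'   treasure counts as found (m).
#' @param alley_axes Five axis angles in degrees, counterclockwise; must be
#'   spaced 72 degrees apart.
#' @param landmarks_present Logical flag per alley marking distal-landmark
#'   availability (all `TRUE` by default; the compelled egocentric task
#'   removes them at the trial level, not here).
#'
#' @return An object of class `maze_geometry` (a named list of the
#'   validated parameters, plus `center = c(0, 0)`).
#' @examples
#' geom <- star_maze()
#' ideal_route(1, 3, geom)$ideal_distance  # 246
#' @export
star_maze <- function(pentagon_circumradius = 23,
                      alley_length = 110,
                      alley_width = 14,
                      treasure_offset = 100,
                      entry_depth = 1,
                      exit_hysteresis = 0.5,
                      capture_radius = 1,
                      alley_axes = 90 + 72 * (0:4),
                      landmarks_present = rep(TRUE, 5)) {
  lens <- c(pentagon_circumradius = pentagon_circumradius,
            alley_length = alley_length, alley_width = alley_width,
            treasure_offset = treasure_offset, entry_depth = entry_depth,
            capture_radius = capture_radius)
  bad <- names(lens)[!is.finite(lens) | lens <= 0]
  if (length(bad))
    stop("maze configuration error: non-positive length in field(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (exit_hysteresis < 0 || exit_hysteresis >= entry_depth)
    stop("maze configuration error: exit_hysteresis must lie in [0, entry_depth)",
         call. = FALSE)
  if (length(alley_axes) != 5L)
    stop("maze configuration error: alley_axes must have exactly 5 angles",
         call. = FALSE)
  gaps <- diff(alley_axes) %% 360
  if (any(abs(gaps - 72) > 1e-8))
    stop("maze configuration error: alley_axes must be spaced 72 degrees apart ",
         "(regular pentagon)", call. = FALSE)
  side <- 2 * pentagon_circumradius * sin(pi / 5)
  if (alley_width >= side)
    stop("maze configuration error: alley_width must be smaller than the ",
         "pentagon side (", signif(side, 4), " m)", call. = FALSE)
  if (treasure_offset > alley_length)
    stop("maze configuration error: treasure_offset exceeds alley_length",
         call. = FALSE)
  if (length(landmarks_present) != 5L || !is.logical(landmarks_present))
    stop("maze configuration error: landmarks_present must be 5 logical flags",
         call. = FALSE)
  structure(list(center = c(0, 0),
                 pentagon_circumradius = pentagon_circumradius,
                 alley_axes = as.numeric(alley_axes),
                 alley_length = alley_length,
                 alley_width = alley_width,
                 treasure_offset = treasure_offset,
                 entry_depth = entry_depth,
                 exit_hysteresis = exit_hysteresis,
                 capture_radius = capture_radius,
                 landmarks_present = landmarks_present),
            class = "maze_geometry")
}

#' @export
print.maze_geometry <- function(x, ...) {
  cat("Star maze: 5 alleys, pentagon circumradius",
      x$pentagon_circumradius, "m,\n  alley length", x$alley_length,
      "m, width", x$alley_width, "m, reward at", x$treasure_offset,
      "m past the hub\n  (direct route between reward positions:",
      2 * (x$pentagon_circumradius + x$treasure_offset), "m)\n")
  invisible(x)
}

# Unit vectors of the five alley axes (5 x 2 matrix).
alley_units <- function(geom) {
  a <- geom$alley_axes * pi / 180
  cbind(cos(a), sin(a))
}

#' Reward / start position inside an alley
#'
#' Position at `treasure_offset` meters past the pentagon boundary along
#' the axis of alley `k`. Both the trial start position and the treasure
#' sit at this depth in their respective alleys.
#'
#' @param k Alley index 1..5.
#' @param geom A [star_maze()] geometry.
#' @param depth Depth past the pentagon boundary (m); defaults to the
#'   reward depth.
#' @return Numeric length-2 point (x, y) in meters.
#' @export
alley_position <- function(k, geom, depth = geom$treasure_offset) {
  stopifnot(k %in% 1:5)
  u <- alley_units(geom)[k, ]
  (geom$pentagon_circumradius + depth) * u
}

# Depth of points past the pentagon boundary within each alley corridor.
# Returns an n x 5 matrix; -Inf where the point is outside corridor k's
# half-width. xy is an n x 2 matrix.
alley_depths <- function(xy, geom) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  u <- alley_units(geom)
  along <- xy %*% t(u)                       # n x 5 signed axial coordinate
  r2 <- rowSums(xy^2)
  perp2 <- pmax(r2 - along^2, 0)
  depth <- along - geom$pentagon_circumradius
  depth[perp2 > (geom$alley_width / 2)^2] <- -Inf
  depth[along < 0] <- -Inf
  depth
}

#' Locate a point within the maze
#'
#' Maps a 2-D point to its region label: `"alley k"` when the point lies
#' within alley k's corridor strictly deeper than `entry_depth` past the
#' pentagon boundary, otherwise `"center"`. A point exactly at the entry
#' threshold resolves to `"center"` (entry requires strictly exceeding the
#' threshold). Points beyond the far end of the alleys are out of bounds.
#'
#' @param point Numeric length-2 point (x, y) in meters.
#' @param geom A [star_maze()] geometry.
#' @return Character scalar: `"center"` or `"alley k"`.
#' @export
locate <- function(point, geom) {
  stopifnot(inherits(geom, "maze_geometry"), length(point) == 2L)
  d <- alley_depths(matrix(point, ncol = 2), geom)[1, ]
  rmax <- geom$pentagon_circumradius + geom$alley_length
  if (sqrt(sum(point^2)) > rmax + 1e-9)
    stop("point out of maze bounds: ", paste(signif(point, 5), collapse = ", "),
         call. = FALSE)
  k <- which(d > geom$entry_depth + 1e-9)
  if (length(k) >= 1L) paste("alley", k[1]) else "center"
}

#' Ideal route between two alleys
#'
#' The ideal route runs from the start position (`treasure_offset` into the
#' start alley) straight to the pentagon center and out to the reward
#' position in the reward alley. Its length is the "ideal distance
#' travelled" of the distance-error formula and its single turn at the
#' center is the "minimum rotations" of the rotation-angle formula. A
#' direct route visits exactly 2 alleys (the start alley and the reward
#' alley).
#'
#' @param start,reward Alley indices 1..5, distinct.
#' @param geom A [star_maze()] geometry.
#' @return A list with `polyline` (3 x 2 matrix: start, center, reward),
#'   `ideal_distance` (m), `min_rotation` (degrees) and
#'   `ideal_alley_count` (always 2).
#' @examples
#' ideal_route(1, 3, star_maze())$min_rotation  # 36 degrees
#' @export
ideal_route <- function(start, reward, geom) {
  stopifnot(inherits(geom, "maze_geometry"))
  if (!(start %in% 1:5) || !(reward %in% 1:5))
    stop("alley indices must be in 1..5", call. = FALSE)
  if (start == reward)
    stop("invalid route: start and reward alleys coincide", call. = FALSE)
  p0 <- alley_position(start, geom)
  p1 <- alley_position(reward, geom)
  poly <- rbind(p0, geom$center, p1)
  # turn at the center between the inbound and outbound headings
  h_in <- atan2(-p0[2], -p0[1])
  h_out <- atan2(p1[2], p1[1])
  turn <- abs(wrap_angle((h_out - h_in) * 180 / pi))
  list(polyline = poly,
       ideal_distance = sum(sqrt(rowSums(diff(poly)^2))),
       min_rotation = turn,
       ideal_alley_count = 2L)
}

# Wrap angles (degrees) to (-180, 180].
wrap_angle <- function(a) {
  a <- (a + 180) %% 360 - 180
  a[a == -180] <- 180
  a
}

# Circular distance between alley indices on the pentagon (0..2).
alley_circular_distance <- function(a, b) {
  d <- abs(a - b) %% 5
  pmin(d, 5 - d)
}
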