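# Systematic sensor placement grids on cylindrical limb surrogates and a
# closed-outline shoe surrogate.
#
# Leg segments carry 12 rings (R1 proximal .. R12 distal) of 16 azimuthal
# slots each (S1 ventral/anterior, numbering increasing towards the
# lateral side), i.e. 192 sensors per leg segment.  Each shoe carries 96
# sensors on three outline rings (default profile 36 + 35 + 25; the sizes
# are configurable but must sum to 96).  Two legs (upper + lower segments)
# and two shoes give the default total of 960 placements.
#
# Mount convention (documented, load-bearing for detection): the sensor
# x axis is the outward surface normal, the y axis is the limb axis
# (pointing proximally, i.e. "up" for a standing posture) and z completes
# the right-handed frame (medio-lateral for ventral placements).  The
# mount rotation is therefore a rotation about the segment's y axis by the
# placement azimuth; note that this necessarily inverts the sensor z axis
# between ventral and dorsal placements.

#' Sensor placement on a segment surrogate
#'
#' @param segment_id Segment the placement binds to (e.g. `"lower_leg"`;
#'   side-suffixed ids are accepted when attaching).
#' @param ring Ring index (legs: 1..12 proximal to distal; shoe: 1..3).
#' @param slot Slot index within the ring (1-based; legs: S1 at azimuth 0,
#'   ventral).
#' @param offset_local 3-vector from the segment origin, segment frame (m).
#' @param mount_rotation 3x3 rotation from the segment frame to the sensor
#'   frame.
#' @param azimuth Azimuth angle (rad) of the placement about the limb axis
#'   (`NA` for shoe outline placements, which store the outline parameter
#'   instead).
#' @param region Optional region label (shoe: `"instep"`, `"heel"`,
#'   `"side"`).
#' @return An object of class `sensor_placement`.
#' @export
sensor_placement <- function(segment_id, ring, slot, offset_local,
                             mount_rotation = diag(3), azimuth = NA_real_,
                             region = NA_character_) {
  structure(list(segment_id = segment_id, ring = as.integer(ring),
                 slot = as.integer(slot),
                 offset_local = as.numeric(offset_local),
                 mount_rotation = mount_rotation, azimuth = azimuth,
                 region = region),
            class = "sensor_placement")
}

#' @export
format.sensor_placement <- function(x, ...) {
  sprintf("%s R%d/S%d", x$segment_id, x$ring, x$slot)
}

#' @export
print.sensor_placement <- function(x, ...) {
  cat("<sensor_placement>", format(x), "\n")
  invisible(x)
}

placement_id <- function(p) sprintf("%s_R%02d_S%02d", p$segment_id, p$ring, p$slot)

leg_mount_rotation <- function(azimuth) {
  # sensor axes in the segment frame (rows): x = outward normal,
  # y = limb axis, z = completes right-handed triad
  rbind(c(cos(azimuth), 0, sin(azimuth)),
        c(0, 1, 0),
        c(-sin(azimuth), 0, cos(azimuth)))
}

new_sensor_grid <- function(placements, geometry, kind) {
  structure(list(placements = placements, geometry = geometry, kind = kind),
            class = "sensor_grid")
}

#' @export
print.sensor_grid <- function(x, ...) {
  cat(sprintf("<sensor_grid> %s: %d placements on %s\n", x$kind,
              length(x$placements),
              paste(unique(vapply(x$placements, `[[`, "", "segment_id")),
                    collapse = ", ")))
  invisible(x)
}

#' Number of placements in a grid
#' @param grid A `sensor_grid`.
#' @return Integer count.
#' @export
n_placements <- function(grid) length(grid$placements)

#' Build the cylindrical sensor grid of a leg segment
#'
#' Places `n_rings x n_slots` sensors on the surface of a cylinder of the
#' given length and radius whose axis is the segment-local y axis with the
#' origin at the proximal joint (the segment extends towards -y).  Rings
#' are equally spaced along the axis at ring-centre heights; slots sit at
#' azimuths `2*pi*(s-1)/n_slots`, with S1 ventral (azimuth 0).
#'
#' @param segment_id `"upper_leg"` or `"lower_leg"` (any id accepted).
#' @param length Cylinder length (m).
#' @param radius Cylinder radius (m).
#' @param n_rings,n_slots Grid dimensions; the defaults give the standard
#'   192 placements.
#' @return A `sensor_grid` with `n_rings * n_slots` placements.
#' @export
#' @examples
#' g <- build_leg_grid("lower_leg")
#' n_placements(g)  # 192
build_leg_grid <- function(segment_id = "lower_leg", length = 0.40,
                           radius = if (grepl("upper", segment_id)) 0.080 else 0.055,
                           n_rings = 12, n_slots = 16) {
  if (length <= 0 || radius <= 0)
    imugait_stop("geometry_error", "cylinder length and radius must be positive")
  placements <- vector("list", n_rings * n_slots)
  i <- 0
  for (r in seq_len(n_rings)) {
    y <- -(r - 0.5) * length / n_rings
    for (s in seq_len(n_slots)) {
      az <- 2 * pi * (s - 1) / n_slots
      i <- i + 1
      placements[[i]] <- sensor_placement(
        segment_id, r, s,
        offset_local = c(radius * cos(az), y, radius * sin(az)),
        mount_rotation = leg_mount_rotation(az),
        azimuth = az)
    }
  }
  new_sensor_grid(placements,
                  geometry = list(length = length, radius = radius,
                                  n_rings = n_rings, n_slots = n_slots),
                  kind = "leg")
}

#' Build the shoe sensor grid
#'
#' Distributes 96 sensors over three rings stacked along the shoe height,
#' each ring following a closed convex outline (an ellipse elongated along
#' the anterior axis).  The default ring sizes are `c(36, 35, 25)`; any
#' profile is accepted as long as it sums to 96.  Placements are labelled
#' by region: `"instep"` (anterior), `"heel"` (posterior) or `"side"`.
#'
#' @param segment_id Usually `"shoe"`.
#' @param ring_sizes Integer vector of sensors per ring, summing to 96.
#' @param half_length,half_width Outline semi-axes (m).
#' @param heights Ring heights above the sole (m), one per ring.
#' @return A `sensor_grid` with 96 placements.
#' @export
build_shoe_grid <- function(segment_id = "shoe", ring_sizes = c(36, 35, 25),
                            half_length = 0.13, half_width = 0.05,
                            heights = c(0.02, 0.05, 0.08)) {
  if (sum(ring_sizes) != 96)
    imugait_stop("config_error", "shoe ring sizes must sum to 96, got %d", sum(ring_sizes))
  if (length(heights) != length(ring_sizes))
    imugait_stop("config_error", "need one ring height per ring")
  placements <- list()
  i <- 0
  for (r in seq_along(ring_sizes)) {
    for (s in seq_len(ring_sizes[r])) {
      u <- 2 * pi * (s - 1) / ring_sizes[r]   # outline parameter, 0 = toe
      pos <- c(half_length * cos(u), heights[r], half_width * sin(u))
      # outward normal of the ellipse outline (in the x-z plane)
      nrm <- c(cos(u) / half_length, 0, sin(u) / half_width)
      nrm <- nrm / sqrt(sum(nrm^2))
      mount <- rbind(c(nrm[1], 0, nrm[3]),
                     c(0, 1, 0),
                     c(-nrm[3], 0, nrm[1]))
      region <- if (cos(u) < -0.6) "heel" else if (cos(u) > 0.6) "instep" else "side"
      i <- i + 1
      placements[[i]] <- sensor_placement(segment_id, r, s, pos, mount,
                                          azimuth = u, region = region)
    }
  }
  new_sensor_grid(placements,
                  geometry = list(ring_sizes = ring_sizes,
                                  half_length = half_length,
                                  half_width = half_width, heights = heights),
                  kind = "shoe")
}

#' Build the full default grid set
#'
#' One leg grid per upper/lower leg segment and side (4 x 192) plus one
#' shoe grid per side (2 x 96): 960 placements in total.
#'
#' @param upper_length,lower_length Segment lengths (m).
#' @return Named list of `sensor_grid` objects, one per segment instance,
#'   with attribute `total` = 960.
#' @export
build_default_grids <- function(upper_length = 0.45, lower_length = 0.43) {
  grids <- list()
  for (side in c("left", "right")) {
    grids[[paste0("upper_leg_", side)]] <-
      build_leg_grid(paste0("upper_leg_", side), length = upper_length, radius = 0.080)
    grids[[paste0("lower_leg_", side)]] <-
      build_leg_grid(paste0("lower_leg_", side), length = lower_length, radius = 0.055)
    grids[[paste0("shoe_", side)]] <- build_shoe_grid(paste0("shoe_", side))
  }
  structure(grids, total = sum(vapply(grids, n_placements, 0L)))
}

#' Rotatory / translatory repositioning subsets
#'
#' `select_rotatory` returns the placements simulating a uniaxial sensor
#' rotation around the limb: all slots of one ring (default R1).
#' `select_translatory` returns the placements simulating a uniaxial
#' translation along the limb: one slot (default S1) across all rings.
#' Shoe grids are rejected: their outline rings are not azimuthally
#' symmetric, so the decomposition is not meaningful there.
#'
#' @param grid A leg `sensor_grid`.
#' @param ring Ring index for the rotatory subset.
#' @param slot Slot index for the translatory subset.
#' @return List of `sensor_placement`s.
#' @export
select_rotatory <- function(grid, ring = 1) {
  if (grid$kind != "leg")
    imugait_stop("unsupported_grid_error",
                 "rotatory/translatory subsets are defined for leg grids only")
  Filter(function(p) p$ring == ring, grid$placements)
}

#' @rdname select_rotatory
#' @export
select_translatory <- function(grid, slot = 1) {
  if (grid$kind != "leg")
    imugait_stop("unsupported_grid_error",
                 "rotatory/translatory subsets are defined for leg grids only")
  Filter(function(p) p$slot == slot, grid$placements)
}

#' Shift a leg placement on its cylinder surface
#'
#' Repositions a sensor by an azimuthal angle and/or an axial offset while
#' keeping it on the cylinder surface, for sensor-repositioning
#' experiments.  Axial shifts leave the synthesised angular velocity
#' invariant on a rigid segment; an azimuthal shift of 180 degrees inverts
#' the sensor z axis (and hence the sign of planar angular velocity).
#'
#' @param placement A leg [sensor_placement()].
#' @param grid The `sensor_grid` the placement belongs to (for geometry).
#' @param d_azimuth Azimuthal shift in degrees.
#' @param d_axial Axial shift in metres (positive towards the proximal
#'   joint); the shifted position must stay on the cylinder (within
#'   `[-length, 0]`).
#' @return A new [sensor_placement()] (ring/slot kept, marked shifted).
#' @export
perturb_placement <- function(placement, grid, d_azimuth = 0, d_axial = 0) {
  if (grid$kind != "leg" || is.na(placement$azimuth))
    imugait_stop("geometry_error", "only leg placements can be perturbed on the cylinder")
  if (d_azimuth == 0 && d_axial == 0) return(placement)
  az <- placement$azimuth + d_azimuth * pi / 180
  y <- placement$offset_local[2] + d_axial
  if (y > 0 || y < -grid$geometry$length)
    imugait_stop("geometry_error",
                 "axial shift %.3g m leaves the cylinder (valid y in [%.3g, 0])",
                 d_axial, -grid$geometry$length)
  r <- grid$geometry$radius
  sensor_placement(placement$segment_id, placement$ring, placement$slot,
                   offset_local = c(r * cos(az), y, r * sin(az)),
                   mount_rotation = leg_mount_rotation(az),
                   azimuth = az, region = placement$region)
}
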