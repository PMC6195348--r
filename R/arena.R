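#' Arena geometry: named zones, bounds and scale
#'
#' Describes a behavioral apparatus as seen by the overhead camera: a set of
#' named polygonal zones (chambers, maze arms, the crossroads center), the
#' outer bounds of the apparatus, optional exclusion areas whose contents
#' interfere with tracking, optional interaction cups (wire cups holding the
#' novel mouse/object in the three-chamber task), and the pixel-to-centimetre
#' scale.
#'
#' Coordinates are in pixels with the origin at the top-left corner, x
#' rightward and y downward, matching the video frames.
#'
#' @param zones named list of polygons; each polygon is a two-column
#'   (x, y) numeric matrix of vertices in pixel coordinates. Zones must not
#'   overlap (zone labels are assigned by first match).
#' @param bounds polygon (two-column matrix) delimiting the apparatus; points
#'   outside it are never accepted as animal positions.
#' @param px_per_cm pixels per centimetre; must be positive.
#' @param exclusions list of polygons to exclude from tracking (e.g. areas
#'   with reflections).
#' @param cups optional named list of cups, each `list(center = c(x, y),
#'   radius_px = r)`; used by [cup_approaches()].
#' @param arms optional arm descriptors for entry-depth classification, as
#'   produced by [arena_epm()]; each is `list(name, class, entrance, axis,
#'   length_px)` where `entrance` is the midpoint of the arm/center border and
#'   `axis` the unit vector pointing into the arm.
#' @return an object of class `arena_geometry`.
#' @seealso [arena_epm()], [arena_three_chamber()], [zone_label()]
#' @export
arena_geometry <- function(zones, bounds, px_per_cm, exclusions = list(),
                           cups = NULL, arms = NULL) {
  if (!is.numeric(px_per_cm) || length(px_per_cm) != 1L || px_per_cm <= 0)
    stop2("px_per_cm must be a single positive number")
  zones <- lapply(zones, as_polygon)
  bounds <- as_polygon(bounds)
  exclusions <- lapply(exclusions, as_polygon)
  bb <- apply(bounds, 2L, range)
  for (nm in names(zones)) {
    zb <- apply(zones[[nm]], 2L, range)
    if (zb[1L, 1L] < bb[1L, 1L] - 1e-9 || zb[2L, 1L] > bb[2L, 1L] + 1e-9 ||
        zb[1L, 2L] < bb[1L, 2L] - 1e-9 || zb[2L, 2L] > bb[2L, 2L] + 1e-9)
      stop2("zone '", nm, "' extends beyond the arena bounds")
  }
  structure(list(zones = zones, bounds = bounds, px_per_cm = px_per_cm,
                 exclusions = exclusions, cups = cups, arms = arms),
            class = "arena_geometry")
}

as_polygon <- function(p) {
  p <- as.matrix(p)
  if (ncol(p) != 2L || nrow(p) < 3L)
    stop2("a polygon needs a two-column (x, y) matrix with >= 3 vertices")
  storage.mode(p) <- "double"
  colnames(p) <- c("x", "y")
  p
}

#' @export
print.arena_geometry <- function(x, ...) {
  cat("Arena geometry:", length(x$zones), "zones, px_per_cm =",
      format(x$px_per_cm), "\n")
  cat("  zones:", paste(names(x$zones), collapse = ", "), "\n")
  if (length(x$exclusions)) cat("  exclusion areas:", length(x$exclusions), "\n")
  if (!is.null(x$cups)) cat("  cups:", paste(names(x$cups), collapse = ", "), "\n")
  invisible(x)
}

#' Point-in-polygon test
#'
#' Thin wrapper over [mgcv::in.out()]. Points exactly on the boundary follow
#' that routine's convention.
#'
#' @param pts two-column (x, y) matrix of query points.
#' @param poly two-column polygon vertex matrix.
#' @return logical vector, `TRUE` for points inside the polygon.
#' @export
point_in_polygon <- function(pts, poly) {
  pts <- matrix(as.numeric(pts), ncol = 2L)
  poly <- as_polygon(poly)
  # in.out wants a closed boundary loop
  if (any(poly[1L, ] != poly[nrow(poly), ])) poly <- rbind(poly, poly[1L, ])
  mgcv::in.out(poly, pts)
}

#' Assign zone labels to positions
#'
#' Each position gets the name of the first zone containing it, or `NA` if it
#' lies in no zone.
#'
#' @param x a [trajectory] or a two-column (x, y) matrix.
#' @param arena an [arena_geometry()].
#' @return character vector of zone names (NA outside all zones).
#' @export
zone_label <- function(x, arena) {
  pts <- if (inherits(x, "trajectory")) cbind(x$x, x$y) else
    matrix(as.numeric(x), ncol = 2L)
  lab <- rep(NA_character_, nrow(pts))
  ok <- !is.na(pts[, 1L]) & !is.na(pts[, 2L])
  for (nm in names(arena$zones)) {
    unassigned <- ok & is.na(lab)
    if (!any(unassigned)) break
    inside <- point_in_polygon(pts[unassigned, , drop = FALSE],
                               arena$zones[[nm]])
    lab[which(unassigned)[inside]] <- nm
  }
  lab
}

rect_poly <- function(x0, y0, x1, y1) {
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

#' Three-chamber social apparatus geometry
#'
#' Builds the geometry of the three-chambered social preference box: three
#' equal chambers side by side along x, with interaction cups centred in the
#' outer chambers.
#'
#' @param width_px,height_px outer dimensions of the box in pixels.
#' @param px_per_cm pixels per centimetre.
#' @param origin pixel coordinates of the top-left corner of the box.
#' @param cup_radius_cm radius of the wire cups (cm).
#' @return an [arena_geometry()] with zones `mouse_chamber`, `center_chamber`,
#'   `object_chamber` and cups `mouse`, `object`.
#' @export
arena_three_chamber <- function(width_px = 480, height_px = 240,
                                px_per_cm = 8, origin = c(10, 10),
                                cup_radius_cm = 5.25) {
  x0 <- origin[1L]; y0 <- origin[2L]
  w3 <- width_px / 3
  zones <- list(
    mouse_chamber  = rect_poly(x0, y0, x0 + w3, y0 + height_px),
    center_chamber = rect_poly(x0 + w3, y0, x0 + 2 * w3, y0 + height_px),
    object_chamber = rect_poly(x0 + 2 * w3, y0, x0 + width_px, y0 + height_px))
  cups <- list(
    mouse  = list(center = c(x0 + w3 / 2, y0 + height_px / 2),
                  radius_px = cup_radius_cm * px_per_cm),
    object = list(center = c(x0 + 2.5 * w3, y0 + height_px / 2),
                  radius_px = cup_radius_cm * px_per_cm))
  arena_geometry(zones, rect_poly(x0, y0, x0 + width_px, y0 + height_px),
                 px_per_cm, cups = cups)
}

#' Elevated plus-maze geometry
#'
#' Builds an EPM as a plus of two open and two closed arms around a central
#' crossroads square. Open arms extend along x, closed arms along y.
#'
#' @param arm_length_cm,arm_width_cm arm dimensions (cm).
#' @param px_per_cm pixels per centimetre.
#' @param center pixel coordinates of the maze center.
#' @return an [arena_geometry()] with zones `open_left`, `open_right`,
#'   `closed_top`, `closed_bottom`, `center`, and arm descriptors used by
#'   [classify_epm_entries()].
#' @export
arena_epm <- function(arm_length_cm = 35, arm_width_cm = 7.5, px_per_cm = 3,
                      center = c(150, 150)) {
  L <- arm_length_cm * px_per_cm
  w <- arm_width_cm * px_per_cm / 2
  cx <- center[1L]; cy <- center[2L]
  zones <- list(
    center        = rect_poly(cx - w, cy - w, cx + w, cy + w),
    open_left     = rect_poly(cx - w - L, cy - w, cx - w, cy + w),
    open_right    = rect_poly(cx + w, cy - w, cx + w + L, cy + w),
    closed_top    = rect_poly(cx - w, cy - w - L, cx + w, cy - w),
    closed_bottom = rect_poly(cx - w, cy + w, cx + w, cy + w + L))
  arms <- list(
    list(name = "open_left",     class = "open",
         entrance = c(cx - w, cy), axis = c(-1, 0), length_px = L),
    list(name = "open_right",    class = "open",
         entrance = c(cx + w, cy), axis = c(1, 0),  length_px = L),
    list(name = "closed_top",    class = "closed",
         entrance = c(cx, cy - w), axis = c(0, -1), length_px = L),
    list(name = "closed_bottom", class = "closed",
         entrance = c(cx, cy + w), axis = c(0, 1),  length_px = L))
  bounds <- rect_poly(cx - w - L, cy - w - L, cx + w + L, cy + w + L)
  arena_geometry(zones, bounds, px_per_cm, arms = arms)
}

#' Y-maze geometry
#'
#' Three arms at 120 degrees around a central triangle, as viewed from above.
#'
#' @param arm_length_cm,arm_width_cm arm dimensions (cm).
#' @param px_per_cm pixels per centimetre.
#' @param center pixel coordinates of the maze center.
#' @return an [arena_geometry()] with zones `center`, `arm_start`, `arm_left`,
#'   `arm_right`.
#' @export
arena_ymaze <- function(arm_length_cm = 33, arm_width_cm = 7.5, px_per_cm = 3,
                        center = c(160, 160)) {
  L <- arm_length_cm * px_per_cm
  w <- arm_width_cm * px_per_cm / 2
  angles <- c(arm_start = 90, arm_left = 210, arm_right = 330) * pi / 180
  arm_poly <- function(th) {
    u <- c(cos(th), sin(th)); v <- c(-sin(th), cos(th))
    r0 <- center + u * w
    rbind(r0 + v * w, r0 + v * w + u * L, r0 - v * w + u * L, r0 - v * w)
  }
  zones <- c(list(center = {
    th <- unname(angles)
    do.call(rbind, lapply(th, function(a) center + c(cos(a), sin(a)) * w * 1.2))
  }), lapply(angles, arm_poly))
  bounds <- rect_poly(center[1L] - w - L, center[2L] - w - L,
                      center[1L] + w + L, center[2L] + w + L)
  arms <- lapply(names(angles), function(nm) {
    th <- angles[[nm]]
    list(name = nm, class = "arm",
         entrance = center + c(cos(th), sin(th)) * w,
         axis = c(cos(th), sin(th)), length_px = L)
  })
  arena_geometry(zones, bounds, px_per_cm, arms = arms)
}

#' Write / read arena geometry as JSON
#'
#' @param arena an [arena_geometry()].
#' @param path file path of the JSON document.
#' @return `write_arena` returns `path` invisibly; `read_arena` returns the
#'   [arena_geometry()].
#' @export
write_arena <- function(arena, path) {
  obj <- list(
    px_per_cm = arena$px_per_cm,
    zones = lapply(arena$zones, function(p) unclass(as.data.frame(p))),
    bounds = unclass(as.data.frame(arena$bounds)),
    exclusions = lapply(arena$exclusions, function(p) unclass(as.data.frame(p))),
    cups = arena$cups, arms = arena$arms)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_arena
#' @export
read_arena <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  as_poly_list <- function(l) lapply(l, function(p) cbind(x = p$x, y = p$y))
  arms <- NULL
  if (!is.null(obj$arms) && length(obj$arms))
    arms <- lapply(obj$arms, function(a) {
      a$entrance <- as.numeric(a$entrance); a$axis <- as.numeric(a$axis); a
    })
  cups <- NULL
  if (!is.null(obj$cups) && length(obj$cups))
    cups <- lapply(obj$cups, function(cc)
      list(center = as.numeric(cc$center), radius_px = cc$radius_px))
  arena_geometry(as_poly_list(obj$zones),
                 cbind(x = obj$bounds$x, y = obj$bounds$y),
                 obj$px_per_cm, exclusions = as_poly_list(obj$exclusions),
                 cups = cups, arms = arms)
}
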