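# Course representation, table/GPX ingestion, profile segmentation, fixtures.

COURSE_COLUMNS <- c("length_m", "grade_angle", "heading_deg",
                    "corner_r_m", "corner_d_m", "corner_theta_deg")

#' Construct a segmented course
#'
#' A course is an ordered sequence of segments, each with a length, a
#' constant grade angle, a compass heading, and optionally a corner
#' specification (inner radius, road width, intersection angle) used by the
#' cornering model. Internally the grade is stored as an angle `gamma`
#' (radians) so that `sin(gamma)` and `cos(gamma)` in the force balance are
#' exact; on file, grades are percentages (`100 * tan(gamma)`).
#'
#' @param length_m segment lengths in metres (all `> 0`).
#' @param grade_pct grades in percent (rise over run); mutually exclusive
#'   with `grade_angle`.
#' @param grade_angle grade angles in radians, `|gamma| < pi/2`.
#' @param heading_deg compass headings in degrees clockwise from north,
#'   normalized to `[0, 360)`.
#' @param corner_r_m inner-bend radius of a corner (m), `NA` if the segment
#'   is not a corner.
#' @param corner_d_m road width at the corner (m), `>= 0`.
#' @param corner_theta_deg interior intersection angle of the two roads
#'   (degrees, in `(0, 180]`; 180 means straight through).
#' @param name course name stored as an attribute.
#' @return A `velo_course`: a `data.frame` with one row per segment and
#'   columns `length_m`, `grade_angle`, `heading_deg`, `corner_r_m`,
#'   `corner_d_m`, `corner_theta_deg`.
#' @examples
#' velo_course(length_m = c(1000, 500), grade_pct = c(0, 5))
#' @seealso [read_course_table()], [make_track_400m()], [course_stats()]
#' @export
velo_course <- function(length_m, grade_pct = NULL, grade_angle = NULL,
                        heading_deg = 0, corner_r_m = NA_real_,
                        corner_d_m = NA_real_, corner_theta_deg = NA_real_,
                        name = "course") {
  n <- length(length_m)
  if (n == 0L) vp_validation_error("a course must have at least one segment")
  if (is.null(grade_angle)) {
    if (is.null(grade_pct)) grade_pct <- 0
    grade_angle <- atan(grade_pct / 100)
  } else if (!is.null(grade_pct)) {
    vp_validation_error("supply exactly one of 'grade_pct' and 'grade_angle'")
  }
  df <- data.frame(
    length_m = as.numeric(length_m),
    grade_angle = rep_len(as.numeric(grade_angle), n),
    heading_deg = rep_len(as.numeric(heading_deg), n) %% 360,
    corner_r_m = rep_len(as.numeric(corner_r_m), n),
    corner_d_m = rep_len(as.numeric(corner_d_m), n),
    corner_theta_deg = rep_len(as.numeric(corner_theta_deg), n)
  )
  validate_course(df)
  structure(df, class = c("velo_course", "data.frame"), name = name)
}

validate_course <- function(df) {
  bad <- which(!is.finite(df$length_m) | df$length_m <= 0)
  if (length(bad))
    vp_validation_error(sprintf(
      "segment %d has non-positive length %g", bad[1], df$length_m[bad[1]]))
  bad <- which(abs(df$grade_angle) >= pi / 2)
  if (length(bad))
    vp_validation_error(sprintf("segment %d grade angle out of (-pi/2, pi/2)",
                                bad[1]))
  has_corner <- !is.na(df$corner_r_m) | !is.na(df$corner_d_m) |
    !is.na(df$corner_theta_deg)
  full_corner <- !is.na(df$corner_r_m) & !is.na(df$corner_d_m) &
    !is.na(df$corner_theta_deg)
  bad <- which(has_corner & !full_corner)
  if (length(bad))
    vp_validation_error(sprintf(
      "segment %d has a partial corner spec (need r, d and theta)", bad[1]))
  idx <- which(full_corner)
  for (i in idx) {
    corner_spec(df$corner_r_m[i], df$corner_d_m[i], df$corner_theta_deg[i])
  }
  invisible(df)
}

#' @export
print.velo_course <- function(x, ...) {
  st <- course_stats(x)
  cat(sprintf("<velo_course> %s: %d segments, %.1f m, ascent %.1f m, mean grade %.3f %%\n",
              attr(x, "name") %||% "course", nrow(x), st$total_length_m,
              st$total_ascent_m, st$mean_grade_pct))
  print(as.data.frame(x), ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize a course
#'
#' @param course a [velo_course()].
#' @return A list with `total_length_m` (sum of segment lengths),
#'   `total_ascent_m` (sum of positive per-segment elevation gains
#'   `s * sin(gamma)`), `total_descent_m`, `mean_grade_pct`
#'   (`100 * ascent / length`), and `n_segments`.
#' @examples
#' course_stats(make_bridge_course())
#' @export
course_stats <- function(course) {
  validate_course(course)
  dz <- course$length_m * sin(course$grade_angle)
  list(
    total_length_m = sum(course$length_m),
    total_ascent_m = sum(pmax(dz, 0)),
    total_descent_m = -sum(pmin(dz, 0)),
    mean_grade_pct = 100 * sum(pmax(dz, 0)) / sum(course$length_m),
    n_segments = nrow(course)
  )
}

#' Read a course from a delimited table
#'
#' The on-disk format is a comma-separated table with a header row and
#' columns `length_m`, `grade_pct` (or `grade_angle`, radians),
#' `heading_deg`, and optionally `corner_r_m`, `corner_d_m`,
#' `corner_theta_deg`. Blank corner cells mean "no corner"; a corner is
#' recognized only when all three corner fields are present on a row.
#'
#' @param path path to the course table.
#' @param name course name; defaults to the file name.
#' @return A [velo_course()].
#' @seealso [write_course_table()]
#' @export
read_course_table <- function(path, name = NULL) {
  if (!file.exists(path))
    vp_validation_error(sprintf("course table '%s' does not exist", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"length_m" %in% names(df))
    vp_format_error("course table is missing required column 'length_m'")
  if (!any(c("grade_pct", "grade_angle") %in% names(df)))
    vp_format_error("course table needs a 'grade_pct' or 'grade_angle' column")
  grab <- function(col, default = NA_real_) {
    if (col %in% names(df)) as.numeric(df[[col]]) else
      rep(default, nrow(df))
  }
  velo_course(
    length_m = as.numeric(df$length_m),
    grade_pct = if ("grade_pct" %in% names(df)) as.numeric(df$grade_pct) else NULL,
    grade_angle = if (!"grade_pct" %in% names(df)) as.numeric(df$grade_angle) else NULL,
    heading_deg = grab("heading_deg", 0),
    corner_r_m = grab("corner_r_m"),
    corner_d_m = grab("corner_d_m"),
    corner_theta_deg = grab("corner_theta_deg"),
    name = name %||% basename(path)
  )
}

#' Write a course to the delimited table format
#'
#' Numeric fields are written with enough digits to round-trip doubles
#' bit-identically through [read_course_table()].
#'
#' @param course a [velo_course()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_course_table <- function(course, path) {
  validate_course(course)
  grade_pct <- 100 * tan(course$grade_angle)
  cols <- list(length_m = course$length_m, grade_pct = grade_pct,
               heading_deg = course$heading_deg,
               corner_r_m = course$corner_r_m,
               corner_d_m = course$corner_d_m,
               corner_theta_deg = course$corner_theta_deg)
  lines <- c(paste(names(cols), collapse = ","),
             apply(do.call(cbind, lapply(cols, fmt_num)), 1,
                   paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Build a raw elevation/heading profile
#'
#' Profile points are the pre-segmentation representation of a course: a
#' table of strictly increasing cumulative along-route distances with the
#' elevation and compass heading at each point.
#'
#' @param distance_m cumulative along-route distance (m), strictly increasing.
#' @param elevation_m elevation (m).
#' @param heading_deg heading at the point (degrees clockwise from north).
#' @return A `data.frame` with columns `distance_m`, `elevation_m`,
#'   `heading_deg`.
#' @seealso [segment_profile()], [read_gpx_profile()]
#' @export
profile_points <- function(distance_m, elevation_m, heading_deg = 0) {
  n <- length(distance_m)
  if (n < 2L) vp_validation_error("a profile needs at least 2 points")
  if (any(diff(distance_m) <= 0))
    vp_validation_error("profile distances must be strictly increasing")
  data.frame(distance_m = as.numeric(distance_m),
             elevation_m = rep_len(as.numeric(elevation_m), n),
             heading_deg = rep_len(as.numeric(heading_deg), n) %% 360)
}

#' Segment an elevation/heading profile into a course
#'
#' Consecutive profile intervals are merged into constant-grade,
#' constant-heading segments: within a run, grade variation at or below
#' `flat_grade_threshold` is flattened to the run's length-weighted mean
#' grade (so a hill becomes a single ramp connecting the bottom and the top
#' of the slope), and heading wiggle at or below
#' `straight_heading_threshold` is treated as a straight. A final pairwise
#' merge pass runs to a fixed point, which makes the operation idempotent:
#' segmenting the reconstruction of the output reproduces it exactly.
#'
#' The grade of an interval is defined as `asin(delta elevation / delta
#' distance)` (distance is along-route), so total length and total ascent
#' are conserved exactly by the length-weighted merge.
#'
#' @param points a [profile_points()] table (>= 2 points).
#' @param flat_grade_threshold maximum grade deviation (as a fraction, e.g.
#'   `0.005` for 0.5 %) merged into one run.
#' @param straight_heading_threshold maximum heading deviation (degrees)
#'   merged into one straight.
#' @param name course name.
#' @return A [velo_course()].
#' @examples
#' pts <- profile_points(seq(0, 1000, by = 100), seq(0, 10, by = 1))
#' segment_profile(pts)  # one 1 % ramp
#' @export
segment_profile <- function(points, flat_grade_threshold = 0.005,
                            straight_heading_threshold = 5,
                            name = "segmented course") {
  if (nrow(points) < 2L) vp_validation_error("a profile needs at least 2 points")
  if (flat_grade_threshold < 0 || straight_heading_threshold < 0)
    vp_validation_error("segmentation thresholds must be >= 0")
  ds <- diff(points$distance_m)
  dz <- diff(points$elevation_m)
  if (any(ds <= 0))
    vp_validation_error("profile distances must be strictly increasing")
  ratio <- dz / ds
  if (any(abs(ratio) >= 1))
    vp_validation_error("profile has |delta elevation| >= delta distance")
  sin_g <- ratio                      # grade measured as sin(gamma)
  hdg <- points$heading_deg[-nrow(points)]

  # greedy forward pass: grow a run while grade and heading stay close to
  # the run's running length-weighted means
  runs <- list()
  cur <- list(s = ds[1], sg = sin_g[1], hd = hdg[1],
              idx = 1L)
  n_int <- length(ds)
  if (n_int > 1L) {
    for (i in 2:n_int) {
      mg <- cur$sg
      mh <- cur$hd
      if (abs(sin_g[i] - mg) <= flat_grade_threshold &&
          abs(angle_diff_deg(hdg[i], mh)) <= straight_heading_threshold) {
        w_old <- cur$s
        cur$s <- cur$s + ds[i]
        cur$sg <- (w_old * cur$sg + ds[i] * sin_g[i]) / cur$s
        cur$hd <- circular_mean_deg(c(cur$hd, hdg[i]), c(w_old, ds[i]))
      } else {
        runs[[length(runs) + 1L]] <- cur
        cur <- list(s = ds[i], sg = sin_g[i], hd = hdg[i])
      }
    }
  }
  runs[[length(runs) + 1L]] <- cur

  s <- vapply(runs, `[[`, numeric(1), "s")
  sg <- vapply(runs, `[[`, numeric(1), "sg")
  hd <- vapply(runs, `[[`, numeric(1), "hd")

  # fixed-point pairwise merge so the operation is idempotent
  repeat {
    if (length(s) < 2L) break
    merged <- FALSE
    i <- 1L
    while (i < length(s)) {
      if (abs(sg[i + 1] - sg[i]) <= flat_grade_threshold &&
          abs(angle_diff_deg(hd[i + 1], hd[i])) <= straight_heading_threshold) {
        tot <- s[i] + s[i + 1]
        sg[i] <- (s[i] * sg[i] + s[i + 1] * sg[i + 1]) / tot
        hd[i] <- circular_mean_deg(c(hd[i], hd[i + 1]), c(s[i], s[i + 1]))
        s[i] <- tot
        s <- s[-(i + 1)]; sg <- sg[-(i + 1)]; hd <- hd[-(i + 1)]
        merged <- TRUE
      } else i <- i + 1L
    }
    if (!merged) break
  }

  velo_course(length_m = s, grade_angle = asin(sg), heading_deg = hd,
              name = name)
}

#' Reconstruct profile points from a segmented course
#'
#' Inverse of [segment_profile()] up to segmentation: emits one point per
#' segment boundary with cumulative distance, accumulated elevation, and the
#' segment heading.
#'
#' @param course a [velo_course()].
#' @return A [profile_points()] table with `nrow(course) + 1` rows.
#' @export
course_to_profile <- function(course) {
  validate_course(course)
  d <- c(0, cumsum(course$length_m))
  z <- c(0, cumsum(course$length_m * sin(course$grade_angle)))
  h <- c(course$heading_deg, course$heading_deg[nrow(course)])
  profile_points(d, z, h)
}

#' Read a GPX track into profile points
#'
#' Parses GPX 1.1 `trkpt` latitude/longitude/elevation triples, computes
#' great-circle along-route distances (haversine, mean Earth radius
#' 6371.0088 km) and forward bearings, and returns a [profile_points()]
#' table suitable for [segment_profile()].
#'
#' @param path path to a GPX file.
#' @return A [profile_points()] table.
#' @export
read_gpx_profile <- function(path) {
  if (!file.exists(path))
    vp_validation_error(sprintf("GPX file '%s' does not exist", path))
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  pts <- xml2::xml_find_all(doc, ".//g:trkpt", ns)
  if (length(pts) < 2L)
    vp_format_error("GPX file contains fewer than 2 track points")
  lat <- deg2rad(as.numeric(xml2::xml_attr(pts, "lat")))
  lon <- deg2rad(as.numeric(xml2::xml_attr(pts, "lon")))
  ele <- as.numeric(xml2::xml_text(xml2::xml_find_first(pts, "./g:ele", ns)))
  if (anyNA(ele)) ele[is.na(ele)] <- 0
  R <- 6371008.8
  dlat <- diff(lat); dlon <- diff(lon)
  a <- sin(dlat / 2)^2 + cos(lat[-length(lat)]) * cos(lat[-1]) * sin(dlon / 2)^2
  step <- 2 * R * asin(pmin(1, sqrt(a)))
  brg <- atan2(sin(dlon) * cos(lat[-1]),
               cos(lat[-length(lat)]) * sin(lat[-1]) -
                 sin(lat[-length(lat)]) * cos(lat[-1]) * cos(dlon))
  brg <- (brg * 180 / pi) %% 360
  profile_points(distance_m = c(0, cumsum(step)),
                 elevation_m = ele,
                 heading_deg = c(brg, brg[length(brg)]))
}

#' The standard 400 m track fixture
#'
#' An athletics-style closed track: two straights and two semicircular
#' curves of inner radius 36.5 m. The total length is 400 m; the summed
#' curve length defaults to the conventional 231.22 m (the printed value for
#' this track layout), leaving 168.78 m of straights split equally. The
#' curve segments carry a corner spec with `r = 36.5`, `d = 0`,
#' `theta = 180`, so the cornering model caps curve speed at
#' `sqrt(mu_sli * g * 36.5)`.
#'
#' Note the curve length is an independent field: `2 * pi * 36.5 = 229.34`
#' differs from the conventional 231.22 m (which is measured at a running
#' offset from the inner kerb); the radius is used only for the speed cap.
#'
#' @param curve_length_m total length of the two curves combined.
#' @param total_length_m total track length.
#' @param curve_radius_m inner radius of the curves.
#' @return A four-segment [velo_course()]: straight, curve, straight, curve.
#' @examples
#' course_stats(make_track_400m())$total_length_m  # 400
#' @export
make_track_400m <- function(curve_length_m = 231.22, total_length_m = 400,
                            curve_radius_m = 36.5) {
  stopifnot_scalar(curve_length_m, "curve_length_m", 0, total_length_m,
                   strict_lower = TRUE)
  straight <- (total_length_m - curve_length_m) / 2
  curve <- curve_length_m / 2
  velo_course(
    length_m = c(straight, curve, straight, curve),
    grade_pct = 0,
    heading_deg = c(0, 90, 180, 270),
    corner_r_m = c(NA, curve_radius_m, NA, curve_radius_m),
    corner_d_m = c(NA, 0, NA, 0),
    corner_theta_deg = c(NA, 180, NA, 180),
    name = "track400"
  )
}

#' The bridge test-course fixture
#'
#' A 1.5 km bridge with 14.8 m of elevation gain, i.e. a mean gradient of
#' `100 * 14.8/1500 = 0.987` %. The default is a single constant-grade
#' ascent (one reported gradient, one segment); `mode = "up_down"` gives a
#' symmetric out-and-over profile (750 m up, 750 m down, net elevation 0)
#' for descent experiments.
#'
#' @param mode `"single"` (default) or `"up_down"`.
#' @param length_m total length (m).
#' @param elevation_m elevation gain to the crest (m).
#' @return A [velo_course()].
#' @examples
#' course_stats(make_bridge_course())$mean_grade_pct  # ~0.987
#' @export
make_bridge_course <- function(mode = c("single", "up_down"),
                               length_m = 1500, elevation_m = 14.8) {
  mode <- match.arg(mode)
  if (mode == "single") {
    velo_course(length_m = length_m,
                grade_pct = 100 * elevation_m / length_m,
                heading_deg = 0, name = "bridge")
  } else {
    half <- length_m / 2
    g <- 100 * elevation_m / half
    velo_course(length_m = c(half, half), grade_pct = c(g, -g),
                heading_deg = 0, name = "bridge (up/down)")
  }
}
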