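test_that("velo_course construction and validation", {
  crs <- velo_course(length_m = c(1000, 500), grade_pct = c(0, 5))
  expect_s3_class(crs, "velo_course")
  expect_equal(nrow(crs), 2)
  expect_equal(course_stats(crs)$total_length_m, 1500)
  expect_equal(crs$grade_angle, atan(c(0, 0.05)))

  expect_error(velo_course(length_m = c(100, -10)),
               class = "velopace_validation_error")
  expect_error(velo_course(numeric(0)), class = "velopace_validation_error")
  # partial corner spec is rejected, full one accepted
  expect_error(velo_course(100, corner_r_m = 10),
               class = "velopace_validation_error")
  crs <- velo_course(100, corner_r_m = 36.5, corner_d_m = 0,
                     corner_theta_deg = 180)
  expect_equal(crs$corner_r_m, 36.5)
})

test_that("course table round-trips bit-identically", {
  path <- withr::local_tempfile(fileext = ".csv")
  for (crs in list(make_track_400m(), make_bridge_course(),
                   make_bridge_course(mode = "up_down"))) {
    write_course_table(crs, path)
    back <- read_course_table(path)
    for (col in c("length_m", "grade_angle", "heading_deg", "corner_r_m",
                  "corner_d_m", "corner_theta_deg"))
      expect_identical(back[[col]], crs[[col]], label = col)
  }
})

test_that("read_course_table validates format and rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("length_m,grade_pct", "1000,0", "500,5"), path)
  crs <- read_course_table(path)
  expect_equal(course_stats(crs)$total_length_m, 1500)
  expect_equal(nrow(crs), 2)

  writeLines(c("length_m,grade_pct", "-10,0"), path)
  expect_error(read_course_table(path), "length",
               class = "velopace_validation_error")

  writeLines(c("grade_pct,heading_deg", "0,0"), path)
  expect_error(read_course_table(path), "length_m",
               class = "velopace_format_error")

  writeLines(c("length_m,grade_pct,corner_r_m,corner_d_m,corner_theta_deg",
               "115.61,0,36.5,0,180", "84.39,0,,,"), path)
  crs <- read_course_table(path)
  expect_equal(crs$corner_r_m, c(36.5, NA))
})

test_that("track fixture matches its stated geometry", {
  crs <- make_track_400m()
  st <- course_stats(crs)
  expect_equal(st$total_length_m, 400)
  is_curve <- !is.na(crs$corner_r_m)
  expect_equal(sum(crs$length_m[is_curve]), 231.22)
  expect_equal(sum(crs$length_m[!is_curve]), 400 - 231.22)
  expect_equal(unique(crs$corner_r_m[is_curve]), 36.5)
  # straights split equally
  expect_equal(diff(crs$length_m[!is_curve]), 0)
})

test_that("bridge fixture matches its stated geometry", {
  crs <- make_bridge_course()
  st <- course_stats(crs)
  expect_equal(st$total_length_m, 1500)
  expect_equal(st$mean_grade_pct, 0.987, tolerance = 5e-4)

  ud <- make_bridge_course(mode = "up_down")
  expect_equal(nrow(ud), 2)
  stu <- course_stats(ud)
  expect_equal(stu$total_ascent_m, stu$total_descent_m)
  expect_equal(sum(ud$length_m * sin(ud$grade_angle)), 0)
})

test_that("course_stats ascent uses s * sin(gamma)", {
  crs <- velo_course(100, grade_angle = atan(0.1))
  expect_equal(course_stats(crs)$total_ascent_m, 100 * sin(atan(0.1)))
  flat <- flat_segment(1000)
  expect_equal(course_stats(flat)$total_ascent_m, 0)
  expect_equal(course_stats(flat)$mean_grade_pct, 0)
})

test_that("segment_profile merges by grade and heading thresholds", {
  # constant 1 % ramp sampled at 10 points -> one segment
  d <- seq(0, 900, by = 100)
  pts <- profile_points(d, 0.01 * d)
  crs <- segment_profile(pts)
  expect_equal(nrow(crs), 1)
  expect_equal(sin(crs$grade_angle), 0.01)

  # hand-traced merge: grades [0, 0.2%, 0, 5%, 5%] with 0.5 % threshold
  grades <- c(0, 0.002, 0, 0.05, 0.05)
  z <- c(0, cumsum(grades * 100))
  pts <- profile_points(seq(0, 500, by = 100), z)
  crs <- segment_profile(pts, flat_grade_threshold = 0.005)
  expect_equal(nrow(crs), 2)
  expect_equal(crs$length_m, c(300, 200))
  expect_equal(sin(crs$grade_angle), c(mean(grades[1:3]), 0.05))

  # 2 degrees of heading wiggle with a 5 degree threshold -> one straight
  pts <- profile_points(seq(0, 400, by = 100), 0,
                        heading_deg = c(0, 2, 358, 1, 0))
  crs <- segment_profile(pts, straight_heading_threshold = 5)
  expect_equal(nrow(crs), 1)

  expect_error(segment_profile(profile_points(c(0, 1), c(0, 0))[1, ]),
               class = "velopace_validation_error")
})

test_that("segmentation conserves length and ascent and is idempotent", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 30
    d <- cumsum(runif(n + 1, 50, 150))
    z <- cumsum(c(0, runif(n, -0.04, 0.06)) *
                  c(1, diff(d)))
    h <- cumsum(c(0, rnorm(n, 0, 3))) %% 360
    pts <- profile_points(d, z, h)
    crs <- segment_profile(pts, 0.01, 8)
    st <- course_stats(crs)
    expect_equal(st$total_length_m, d[n + 1] - d[1])
    expect_equal(sum(crs$length_m * sin(crs$grade_angle)), z[n + 1] - z[1])
    # idempotence: re-segmenting the reconstruction changes nothing
    again <- segment_profile(course_to_profile(crs), 0.01, 8)
    expect_equal(nrow(again), nrow(crs))
    expect_equal(again$grade_angle, crs$grade_angle)
    expect_equal(again$length_m, crs$length_m)
    expect_equal(again$heading_deg, crs$heading_deg, tolerance = 1e-9)
  }
})

test_that("GPX tracks map to profile points", {
  gpx <- c('<?xml version="1.0"?>',
           '<gpx version="1.1" xmlns="http://www.topografix.com/GPX/1/1">',
           "<trk><trkseg>",
           '<trkpt lat="48.0000" lon="2.0000"><ele>100</ele></trkpt>',
           '<trkpt lat="48.0010" lon="2.0000"><ele>105</ele></trkpt>',
           '<trkpt lat="48.0020" lon="2.0000"><ele>110</ele></trkpt>',
           "</trkseg></trk></gpx>")
  path <- withr::local_tempfile(fileext = ".gpx")
  writeLines(gpx, path)
  pts <- read_gpx_profile(path)
  expect_equal(nrow(pts), 3)
  # 0.001 deg of latitude is ~111.2 m, heading due north
  expect_equal(diff(pts$distance_m), rep(111.2, 2), tolerance = 0.01)
  expect_equal(pts$heading_deg, rep(0, 3))
  expect_equal(pts$elevation_m, c(100, 105, 110))
  crs <- segment_profile(pts)
  expect_equal(nrow(crs), 1)
})
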