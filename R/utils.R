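# Internal helpers: error conditions and angle arithmetic.

vp_error <- function(msg, class) {
  stop(structure(
    class = c(class, "velopace_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

vp_validation_error <- function(msg) vp_error(msg, "velopace_validation_error")
vp_format_error     <- function(msg) vp_error(msg, "velopace_format_error")
vp_numerical_error  <- function(msg) vp_error(msg, "velopace_numerical_error")

deg2rad <- function(x) x * pi / 180

# Signed smallest angular difference a - b in (-180, 180].
angle_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

# Circular mean of headings (degrees clockwise from north), weighted.
circular_mean_deg <- function(x, w = rep(1, length(x))) {
  th <- deg2rad(x)
  m <- atan2(sum(w * sin(th)), sum(w * cos(th))) * 180 / pi
  m %% 360
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopifnot_scalar <- function(x, name, lower = -Inf, upper = Inf,
                             strict_lower = FALSE) {
  if (!is_scalar_number(x))
    vp_validation_error(sprintf("'%s' must be a finite numeric scalar", name))
  lo_ok <- if (strict_lower) x > lower else x >= lower
  if (!lo_ok || x > upper)
    vp_validation_error(sprintf(
      "'%s' = %g outside its valid range %s%g, %g]",
      name, x, if (strict_lower) "(" else "[", lower, upper))
  invisible(x)
}

# Full-precision numeric formatting that round-trips doubles exactly.
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("")
    s <- sprintf("%.17g", v)
    # prefer the shortest representation that still round-trips
    for (d in 1:16) {
      t <- sprintf("%.*g", d, v)
      if (as.numeric(t) == v) return(t)
    }
    s
  }, character(1))
  out
}
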