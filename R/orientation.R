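#' Orientation grid for population responses
#'
#' Channels uniformly tile the circular orientation axis \eqn{[-180, 180)}
#' degrees. The default 1-degree spacing gives 360 channels, comfortably finer
#' than the 10-degree bins used for analysis.
#'
#' @param spacing Channel spacing in degrees; must divide 360 exactly.
#' @return A list with `theta` (channel orientations in degrees) and
#'   `spacing`, of class `orientation_grid`.
#' @export
#' @examples
#' g <- orientation_grid()
#' length(g$theta) # 360
orientation_grid <- function(spacing = 1) {
  if (!is.numeric(spacing) || length(spacing) != 1 || spacing <= 0 ||
      abs(360 / spacing - round(360 / spacing)) > 1e-9) {
    stop("`spacing` must be a positive number that divides 360 exactly")
  }
  structure(
    list(theta = seq(-180, 180 - spacing, by = spacing), spacing = spacing),
    class = "orientation_grid"
  )
}

#' Wrap angles into (-180, 180]
#'
#' @param x Numeric vector of angles in degrees.
#' @return Angles wrapped to the half-open interval (-180, 180].
#' @export
#' @examples
#' wrap_angle(c(190, -181, 360, 180))
wrap_angle <- function(x) {
  w <- x %% 360
  ifelse(w > 180, w - 360, w)
}

# Minimal absolute circular distance (period 360).
circ_dist <- function(a, b) abs(wrap_angle(a - b))

same_grid <- function(a, b) {
  isTRUE(all.equal(a$spacing, b$spacing)) &&
    length(a$theta) == length(b$theta)
}
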