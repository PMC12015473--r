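#' Shape specification with closed-form ground truth
#'
#' Describes an analytic bud-like shape used by the synthetic scene renderer.
#' Stadium (a rectangle capped by two semicircles), ellipse and circle all
#' admit exact (or, for the ellipse perimeter, Ramanujan-approximate) closed
#' forms for area and perimeter, which makes them oracles for the image
#' morphometrics: a rendered shape's measured features can be compared
#' against `area_cm2`/`perimeter_cm` without any reference software.
#'
#' @param kind one of `"stadium"`, `"ellipse"`, `"circle"`.
#' @param length_cm overall caliper length L in cm (for a circle, the
#'   diameter). Must satisfy `length_cm >= width_cm > 0`.
#' @param width_cm overall caliper width W in cm.
#' @param center_px numeric length-2, shape centre as (row, col) in pixels.
#' @param angle_deg rotation of the long axis, degrees counter-clockwise
#'   from the column (horizontal) axis.
#'
#' @return An object of class `shape_spec`: a list with the inputs plus
#'   `area_cm2` and `perimeter_cm` closed forms.
#' @examples
#' sp <- shape_spec("stadium", 2.65, 0.35, center_px = c(500, 500))
#' sp$area_cm2      # a*W + pi*(W/2)^2 with a = L - W
#' sp$perimeter_cm  # 2*a + pi*W
#' @export
shape_spec <- function(kind = c("stadium", "ellipse", "circle"),
                       length_cm, width_cm,
                       center_px, angle_deg = 0) {
  kind <- match.arg(kind)
  if (kind == "circle") width_cm <- length_cm
  stopifnot(is.numeric(length_cm), is.numeric(width_cm),
            width_cm > 0, length_cm >= width_cm,
            length(center_px) == 2L)
  tr <- shape_truth(kind, length_cm, width_cm)
  structure(list(kind = kind, length_cm = length_cm, width_cm = width_cm,
                 center_px = as.numeric(center_px),
                 angle_deg = as.numeric(angle_deg),
                 area_cm2 = tr$area, perimeter_cm = tr$perimeter),
            class = "shape_spec")
}

# Closed forms: stadium A = aW + pi (W/2)^2, P = 2a + pi W with a = L - W;
# ellipse A = pi a b, P by Ramanujan's second approximation.
shape_truth <- function(kind, L, W) {
  switch(kind,
    stadium = {
      a <- L - W
      list(area = a * W + pi * (W / 2)^2, perimeter = 2 * a + pi * W)
    },
    ellipse = {
      a <- L / 2; b <- W / 2
      h <- ((a - b) / (a + b))^2
      list(area = pi * a * b,
           perimeter = pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h))))
    },
    circle = {
      r <- L / 2
      list(area = pi * r^2, perimeter = 2 * pi * r)
    })
}

# Inside test for supersampled rasterization. (u, v) are coordinates in cm
# in the shape frame: u along the long axis, origin at the centre.
shape_inside <- function(shape, u, v) {
  L <- shape$length_cm; W <- shape$width_cm
  switch(shape$kind,
    stadium = {
      a <- L - W
      du <- pmax(abs(u) - a / 2, 0)
      du * du + v * v <= (W / 2)^2
    },
    ellipse = {
      (u / (L / 2))^2 + (v / (W / 2))^2 <= 1
    },
    circle = {
      u * u + v * v <= (L / 2)^2
    })
}
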