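## Groove-projection geometry.
##
## All arc positions of one antler live on a shared burr-aligned coordinate
## circle of circumference C (default 360, so positions read directly as
## degrees). Convention: left antler viewed along the pedicle axis from
## distal; 0 at the supraorbital ridge (SR), increasing toward the temporal
## ridge (TR, the lateral side). Right antlers are mirrored on input.

arc_mod <- function(x, C) ((x %% C) + C) %% C

## signed circular difference a - b in (-C/2, C/2]
arc_signed <- function(a, b, C) {
  d <- arc_mod(a - b, C)
  ifelse(d > C / 2, d - C, d)
}

## is position p inside the arc swept from `from` to `to` in +direction?
in_arc <- function(p, from, to, C) {
  arc_mod(p - from, C) < arc_mod(to - from, C)
}

#' Opposite point on a cross-section circumference
#'
#' The point dividing the circumference into two equal arcs from the given
#' position: the branching direction of a tine is the opposite point of its
#' fork ridge on the tine's cross-section.
#'
#' @param ridge Arc position in \[0, C).
#' @param C Circumference (positive).
#' @return Arc position `(ridge + C/2) mod C`.
#' @export
#' @examples
#' opposite_point(0, 12)  # 6
#' opposite_point(9, 12)  # 3
opposite_point <- function(ridge, C = 360) {
  if (any(C <= 0)) stop("circumference must be positive")
  arc_mod(ridge + C / 2, C)
}

#' Prorate a position across an overlapping proximal tine
#'
#' When a point drawn down the grooves lands on a more proximal tine
#' instead of reaching the burr, it is carried across by proportional
#' allotment centred on the groove-boundary: with x the arc from the fork
#' ridge to the point and y the arc from the point to the groove-boundary
#' (both on the side carrying the point), the carried point sits at
#' `X = x (X + Y) / (x + y)` from the ridge's opposite point on the arc
#' running from the opposite point to the groove-boundary. The
#' groove-boundary is the fixed point of the prorating; the ridge maps to
#' its opposite point; the degenerate case `x + y = 0` returns the
#' boundary.
#'
#' @param alpha_before Arc position of the point, on one of the two arcs
#'   between `ridge` and `boundary`.
#' @param ridge Fork ridge arc position.
#' @param boundary Groove-boundary arc position.
#' @param C Circumference.
#' @param opposite Opposite point of the ridge; supplied for emphasis of
#'   the construction, must equal `opposite_point(ridge, C)`.
#' @return The prorated arc position on the arc from `opposite` to
#'   `boundary` that avoids the ridge.
#' @export
remap_across_tine <- function(alpha_before, ridge, boundary, C = 360,
                              opposite = opposite_point(ridge, C)) {
  if (C <= 0) stop("circumference must be positive")
  if (abs(arc_signed(opposite, opposite_point(ridge, C), C)) > 1e-9)
    stop("'opposite' must be the opposite point of 'ridge'")
  a <- arc_mod(alpha_before, C); r <- arc_mod(ridge, C)
  b <- arc_mod(boundary, C); o <- opposite

  span_pos <- arc_mod(b - r, C)           # arc r -> b in + direction
  if (span_pos == 0 || span_pos == C)     # ridge on the boundary
    return(b)
  x_pos <- arc_mod(a - r, C)
  if (x_pos <= span_pos) {                # point on the + side
    x <- x_pos
    xy <- span_pos
    dir <- +1
  } else {                                # point on the - side
    x <- arc_mod(r - a, C)
    xy <- C - span_pos
    dir <- -1
  }
  # shadow arc: from the opposite point to the boundary, avoiding the ridge
  # (never longer than C/2 since the ridge is opposite the arc's origin)
  S <- abs(arc_signed(b, o, C))
  shadow_dir <- if (in_arc(r, o, b, C)) -1 else +1
  arc_mod(o + shadow_dir * x * S / xy, C)
}

#' Inverse of [remap_across_tine()]
#'
#' Maps a position on the shadow arc (from the ridge's opposite point to
#' the groove-boundary) back to the arc carrying the overlapping tine, on
#' the requested side.
#'
#' @inheritParams remap_across_tine
#' @param alpha_after Position on the shadow arc.
#' @param side `+1` (the arc from ridge to boundary in increasing
#'   direction) or `-1`.
#' @return The pre-image arc position.
#' @export
unmap_across_tine <- function(alpha_after, ridge, boundary, C = 360,
                              side = +1) {
  r <- arc_mod(ridge, C); b <- arc_mod(boundary, C)
  o <- opposite_point(r, C)
  span_pos <- arc_mod(b - r, C)
  if (span_pos == 0 || span_pos == C) stop("degenerate fork: ridge on boundary")
  S <- abs(arc_signed(b, o, C))
  shadow_dir <- if (in_arc(r, o, b, C)) -1 else +1
  X <- arc_mod(shadow_dir * (alpha_after - o), C)
  if (X > S + 1e-9) stop("alpha_after is not on the shadow arc")
  xy <- if (side > 0) span_pos else C - span_pos
  x <- X * xy / S
  arc_mod(r + side * x, C)
}
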