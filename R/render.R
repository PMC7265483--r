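## SVG rendering of burr diagrams. Angles are drawn with 0 deg at the top
## (SR) and increasing clockwise (toward TR, the lateral side of a left
## antler viewed from distal).

svg_point <- function(angle, radius, cx = 150, cy = 150) {
  rad <- (angle - 90) * pi / 180
  c(x = cx + radius * cos(rad), y = cy + radius * sin(rad))
}

.zone_palette <- c("#e41a1c", "#377eb8", "#4daf4a", "#984ea3", "#ff7f00",
                   "#a65628", "#f781bf", "#999999", "#66c2a5", "#fc8d62",
                   "#8da0cb", "#e78ac3", "#a6d854", "#ffd92f")

#' Render a burr diagram as SVG
#'
#' Draws the diagram: the large circle is the burr cross-section, dots are
#' the branching directions of the elements, short lines orthogonal to the
#' circle are the fork positions, painted sectors are the element zones,
#' the central dot is the antler base, and thin lines outside the circle
#' mark the skull indices.
#'
#' @param diagram A `burr_diagram`.
#' @param file Optional path; when given the SVG is written there.
#' @return The SVG document as a single string (invisibly when `file` is
#'   given).
#' @export
render_diagram <- function(diagram, file = NULL) {
  stopifnot(inherits(diagram, "burr_diagram"))
  R <- 100; cx <- 150; cy <- 150
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<svg xmlns="http://www.w3.org/2000/svg" width="300" height="300" viewBox="0 0 300 300">',
    sprintf('<title>burr diagram: %s</title>',
            gsub("&", "&amp;", diagram$hierarchy)))

  # zones as filled sectors
  z <- diagram$zones
  for (i in seq_len(nrow(z))) {
    a0 <- z$start[i]; a1 <- z$end[i]
    sweep <- arc_mod(a1 - a0, 360)
    if (sweep == 0) sweep <- 360  # full-circle zone (spike antler)
    col <- .zone_palette[(i - 1L) %% length(.zone_palette) + 1L]
    if (sweep >= 360 - 1e-9) {
      out <- c(out, sprintf(
        '<circle class="zone" data-element="%s" cx="%g" cy="%g" r="%g" fill="%s" fill-opacity="0.35"/>',
        z$element[i], cx, cy, R, col))
      next
    }
    p0 <- svg_point(a0, R); p1 <- svg_point(a1, R)
    large <- if (sweep > 180) 1 else 0
    out <- c(out, sprintf(
      '<path class="zone" data-element="%s" d="M %g %g L %.3f %.3f A %g %g 0 %d 1 %.3f %.3f Z" fill="%s" fill-opacity="0.35" stroke="none"/>',
      z$element[i], cx, cy, p0["x"], p0["y"], R, R, large,
      p1["x"], p1["y"], col))
  }

  # burr circle and central antler-base dot
  out <- c(out,
    sprintf('<circle class="burr" cx="%g" cy="%g" r="%g" fill="none" stroke="black" stroke-width="1.5"/>', cx, cy, R),
    sprintf('<circle class="base" cx="%g" cy="%g" r="3" fill="black"/>', cx, cy))

  # fork positions: short ticks orthogonal to (crossing) the circle
  for (nm in names(diagram$fork_positions)) {
    for (ang in diagram$fork_positions[[nm]]) {
      pin <- svg_point(ang, R - 8); pout <- svg_point(ang, R + 8)
      out <- c(out, sprintf(
        '<line class="fork" data-fork="%s" x1="%.3f" y1="%.3f" x2="%.3f" y2="%.3f" stroke="black" stroke-width="1.2"/>',
        nm, pin["x"], pin["y"], pout["x"], pout["y"]))
    }
  }

  # branching directions: dots on the circle with element labels
  for (nm in names(diagram$branching_directions)) {
    ang <- diagram$branching_directions[[nm]]
    p <- svg_point(ang, R)
    lab <- svg_point(ang, R - 18)
    out <- c(out, sprintf(
      '<circle class="dot" data-element="%s" cx="%.3f" cy="%.3f" r="3.5" fill="black"/>',
      nm, p["x"], p["y"]),
      sprintf('<text class="label" x="%.3f" y="%.3f" font-size="9" text-anchor="middle">%s</text>',
              lab["x"], lab["y"], nm))
  }

  # skull indices outside the circle
  for (nm in names(diagram$skull_marks)) {
    ang <- diagram$skull_marks[[nm]]
    p0 <- svg_point(ang, R + 4); p1 <- svg_point(ang, R + 16)
    lab <- svg_point(ang, R + 28)
    out <- c(out, sprintf(
      '<line class="skull" data-index="%s" x1="%.3f" y1="%.3f" x2="%.3f" y2="%.3f" stroke="grey" stroke-width="0.8"/>',
      nm, p0["x"], p0["y"], p1["x"], p1["y"]),
      sprintf('<text class="skull-label" x="%.3f" y="%.3f" font-size="8" text-anchor="middle" fill="grey">%s</text>',
              lab["x"], lab["y"], nm))
  }

  out <- c(out, sprintf(
    '<text class="hierarchy" x="%g" y="%g" font-size="8" text-anchor="middle">%s</text>',
    cx, cy + 14, gsub("&", "&amp;", diagram$hierarchy)), "</svg>")
  doc <- paste(out, collapse = "\n")
  if (!is.null(file)) {
    writeLines(doc, file)
    return(invisible(doc))
  }
  doc
}
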