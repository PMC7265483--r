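#' Construct a tine-tree node
#'
#' A tine tree is the rooted branching structure of one antler. Every node
#' is a segment (the root is the antler base above the burr); every
#' internal node carries a fork record placed at its distal end: the fork
#' ridge and groove-boundary arc positions (on the shared coordinate
#' circle) and, per child, the direction anchor — the fork point as seen on
#' that child's cross-section, whose opposite point is the child's
#' branching direction. Trifurcations are encoded as two nested
#' bifurcations.
#'
#' @param code Element code (the root of a branched antler uses `"base"`).
#' @param category One of `"tine"`, `"beam"`, `"process"`, or `"base"`.
#' @param length,diameter Positive segment length and basal diameter (same
#'   units).
#' @param fork `NULL` for a terminal segment, else a list with `ridge`,
#'   `boundary` and `child_ridge` (numeric length-2: direction anchors of
#'   the two children).
#' @param children List of 0 or 2 child `tine_node`s. The first child owns
#'   the arc from `ridge` to `boundary` in increasing direction, the second
#'   the complementary arc.
#' @return A `tine_node` list.
#' @export
tine_node <- function(code, category = "tine", length = 100, diameter = 20,
                      fork = NULL, children = list()) {
  stopifnot(length(children) %in% c(0L, 2L))
  if (length(children) == 2L && is.null(fork))
    stop("internal node needs a fork record")
  if (length(children) == 0L && !is.null(fork))
    stop("terminal node cannot carry a fork")
  if (length <= 0 || diameter <= 0)
    stop("length and diameter must be positive")
  structure(list(code = code, category = category, length = length,
                 diameter = diameter, fork = fork, children = children),
            class = "tine_node")
}

#' Construct a tine tree
#'
#' @param root The root `tine_node` (the antler base, or the single element
#'   of a spike antler).
#' @param circumference Shared coordinate circumference (default 360, so arc
#'   positions read as degrees).
#' @param side `"left"` or `"right"`.
#' @return A `tine_tree`.
#' @export
tine_tree <- function(root, circumference = 360, side = "left") {
  stopifnot(side %in% c("left", "right"))
  if (circumference <= 0) stop("circumference must be positive")
  tr <- structure(list(root = root, circumference = circumference,
                       side = side), class = "tine_tree")
  validate_tine_tree(tr)
  tr
}

#' Validate a tine tree
#'
#' Checks that every internal node bifurcates, that lengths and diameters
#' are positive, and that all fork arc positions lie in \[0, C).
#'
#' @param tree A `tine_tree`.
#' @return `tree`, invisibly.
#' @export
validate_tine_tree <- function(tree) {
  C <- tree$circumference
  walk <- function(node) {
    if (node$length <= 0 || node$diameter <= 0)
      stop("non-positive length/diameter at element ", node$code)
    if (length(node$children) == 2L) {
      f <- node$fork
      if (is.null(f$ridge) || is.null(f$boundary) ||
          length(f$child_ridge) != 2L)
        stop("malformed fork record at element ", node$code)
      pos <- c(f$ridge, f$boundary, f$child_ridge)
      if (any(pos < 0 | pos >= C))
        stop("fork arc positions out of [0, C) at element ", node$code)
      lapply(node$children, walk)
    } else if (length(node$children) != 0L) {
      stop("every fork must be a bifurcation (element ", node$code, ")")
    }
    invisible(NULL)
  }
  walk(tree$root)
  invisible(tree)
}

#' @export
print.tine_tree <- function(x, ...) {
  cat("tine tree (", x$side, "antler, C =", x$circumference, "):",
      hierarchy_string(x), "\n")
  invisible(x)
}

## flat index of nodes: list of (node, path = list of (parent node, which
## child)) keyed by code
index_tine_tree <- function(tree) {
  out <- list()
  walk <- function(node, ancestors) {
    out[[length(out) + 1L]] <<- list(node = node, ancestors = ancestors)
    if (length(node$children) == 2L) {
      for (i in 1:2)
        walk(node$children[[i]],
             c(ancestors, list(list(node = node, which = i))))
    }
  }
  walk(tree$root, list())
  names(out) <- vapply(out, function(e) e$node$code, "")
  out
}

## element codes: every coded non-root node; for a childless coded root
## (spike antler) the root itself
element_codes <- function(tree) {
  idx <- index_tine_tree(tree)
  codes <- names(idx)[-1L]
  if (!length(codes) && !identical(tree$root$code, "base"))
    codes <- tree$root$code
  codes
}

## arc (from, to) in + direction owned by child `which` of a fork
child_arc <- function(fork, which, C) {
  if (which == 1L) c(fork$ridge, fork$boundary)
  else c(fork$boundary, fork$ridge)
}

## carry an arc position down from just above `ancestors` to the burr:
## at each ancestor fork (deepest first is last in the list), positions
## falling in the arc of the sibling (the more proximal tine the point
## overlaps) are prorated across it
descend_position <- function(pos, ancestors, C) {
  for (a in rev(ancestors)) {
    f <- a$node$fork
    sib <- 3L - a$which
    arc <- child_arc(f, sib, C)
    if (in_arc(pos, arc[1L], arc[2L], C) &&
        !isTRUE(all.equal(arc_mod(pos - arc[1L], C), 0))) {
      pos <- remap_across_tine(pos, f$ridge, f$boundary, C)
    }
  }
  pos
}

#' Project an element's branching direction onto the burr
#'
#' The branching direction is the opposite point of the element's fork
#' (on the element's own cross-section, encoded as the direction anchor)
#' carried down the grooves to the burr, prorated across each overlapping
#' more-proximal tine on the way.
#'
#' @param tree A `tine_tree`.
#' @param element Element code.
#' @return Burr angle in degrees \[0, 360), in left-antler convention
#'   (mirrored for right antlers).
#' @export
project_to_burr <- function(tree, element) {
  C <- tree$circumference
  idx <- index_tine_tree(tree)
  hit <- which(names(idx) == element)
  if (!length(hit)) stop("element absent from tree: ", element)
  entry <- idx[[hit[1L]]]
  if (!length(entry$ancestors))
    stop("the root segment has no branching direction")
  birth <- entry$ancestors[[length(entry$ancestors)]]
  anchor <- birth$node$fork$child_ridge[[birth$which]]
  pos <- opposite_point(anchor, C)
  # proration happens at forks below the birth fork
  pos <- descend_position(pos, entry$ancestors[-length(entry$ancestors)], C)
  to_burr_angle(pos, C, tree$side)
}

#' Project a fork's two burr positions
#'
#' For one fork two positions reach the burr: the fork point traced along
#' the grooves on each side — the ridge-side trace and the
#' groove-boundary-side trace. They bound the zones of the fork's two
#' elements; they coincide when the ridge sits on the groove-boundary.
#'
#' @param tree A `tine_tree`.
#' @param fork Fork id: `"A/B"` where A and B are the fork's child element
#'   codes (in tree order).
#' @return Named numeric: `lateral` (ridge-side) and `medial`
#'   (boundary-side) burr angles in degrees.
#' @export
project_fork <- function(tree, fork) {
  C <- tree$circumference
  idx <- index_tine_tree(tree)
  ids <- vapply(idx, function(e) fork_id(e$node), "")
  hit <- which(ids == fork)
  if (!length(hit)) stop("unknown fork: ", fork)
  entry <- idx[[hit[1L]]]
  f <- entry$node$fork
  r <- descend_position(f$ridge, entry$ancestors, C)
  b <- descend_position(f$boundary, entry$ancestors, C)
  c(lateral = to_burr_angle(r, C, tree$side),
    medial = to_burr_angle(b, C, tree$side))
}

fork_id <- function(node) {
  if (length(node$children) != 2L) return(NA_character_)
  paste(node$children[[1L]]$code, node$children[[2L]]$code, sep = "/")
}

to_burr_angle <- function(pos, C, side) {
  ang <- arc_mod(pos, C) * 360 / C
  if (side == "right") ang <- arc_mod(360 - ang, 360)
  ang
}

#' Zones of the antler elements on the burr circle
#'
#' The projected fork positions cut the burr circle into angular intervals;
#' each interval is the zone of the element whose branching direction falls
#' inside it. Zones partition the circle. Inconsistent geometry (an
#' interval holding zero or several branching directions) is an error.
#'
#' @param tree A `tine_tree`.
#' @return A data.frame with `element`, `start`, `end` (degrees; the zone
#'   is the arc from `start` to `end` in increasing direction, wrapping at
#'   360).
#' @export
compute_zones <- function(tree) {
  C <- tree$circumference
  codes <- element_codes(tree)
  idx <- index_tine_tree(tree)
  forks <- Filter(function(e) length(e$node$children) == 2L, idx)
  if (!length(forks)) {
    if (length(codes) != 1L) stop("inconsistent spike antler")
    return(data.frame(element = codes, start = 0, end = 360,
                      stringsAsFactors = FALSE))
  }
  marks <- sort(unique(round(unlist(lapply(names(forks), function(nm) {
    project_fork(tree, fork_id(idx[[nm]]$node))
  })), 9)))
  dirs <- vapply(codes, function(cd) project_to_burr(tree, cd), 0)
  k <- length(marks)
  if (k != length(codes))
    stop("overlapping fork positions: ", k, " marks for ",
         length(codes), " elements")
  starts <- marks
  ends <- c(marks[-1L], marks[1L] + 360)
  owner <- character(k)
  for (i in seq_len(k)) {
    inside <- which(in_arc(dirs, starts[i], ends[i], 360))
    if (length(inside) != 1L)
      stop("zone [", starts[i], ", ", ends[i] %% 360, ") holds ",
           length(inside), " branching directions; inconsistent geometry")
    owner[i] <- codes[inside]
  }
  data.frame(element = owner, start = starts, end = ends %% 360,
             stringsAsFactors = FALSE)
}

#' Nested parenthesisation of the branching hierarchy
#'
#' @param tree A `tine_tree`.
#' @return A string such as `"(B,(T,(CI,CO)H)L)"`: each fork as
#'   `(child1,child2)`, a branching element's own code appended after its
#'   fork.
#' @export
hierarchy_string <- function(tree) {
  render <- function(node) {
    if (length(node$children) == 2L) {
      inner <- paste0("(", render(node$children[[1L]]), ",",
                      render(node$children[[2L]]), ")")
      if (identical(node$code, "base")) inner else paste0(inner, node$code)
    } else node$code
  }
  render(tree$root)
}

#' Default skull-index marks on the burr circle
#'
#' Left-antler convention: 0 deg at the supraorbital ridge (SR), angles
#' increasing toward the temporal ridge (TR) on the lateral side. The
#' remaining indices take their typical positions: the arterial impression
#' (IFST) slightly medial of SR, the orbital landmark SPO between SR and
#' TR, the muscle-origin landmarks LMOF and PEOI behind TR, and the nerve
#' field boundary (BN) at the back of the pedicle.
#'
#' @return Named numeric vector of degrees.
#' @export
default_skull_marks <- function() {
  c(SR = 0, SPO = 45, TR = 90, LMOF = 120, PEOI = 150, BN = 180, IFST = 346)
}

#' Build the burr diagram of an antler
#'
#' Assembles the circular representation of one antler's branching
#' structure: branching-direction points, fork positions, zones, the
#' branching hierarchy, and the skull indices on the burr cross-section.
#' Right antlers are mirrored into the left-antler convention so diagrams
#' are directly comparable.
#'
#' @param tree A `tine_tree`.
#' @param skull_marks Named numeric vector of skull-index angles (degrees);
#'   must include at least `SR` and `TR`.
#' @return An object of class `burr_diagram`: list with
#'   `branching_directions` (named degrees), `fork_positions` (named list
#'   of `c(lateral, medial)`), `zones` (data.frame), `hierarchy` (string),
#'   `skull_marks`, `side` (always `"left"` after mirroring) and
#'   `mirrored`.
#' @export
build_diagram <- function(tree, skull_marks = default_skull_marks()) {
  validate_tine_tree(tree)
  if (!all(c("SR", "TR") %in% names(skull_marks)))
    stop("skull marks must include at least SR and TR")
  codes <- element_codes(tree)
  idx <- index_tine_tree(tree)
  forks <- Filter(function(e) length(e$node$children) == 2L, idx)

  dirs <- if (length(forks)) {
    vapply(codes, function(cd) project_to_burr(tree, cd), 0)
  } else stats::setNames(numeric(0), character(0))
  fp <- lapply(forks, function(e) project_fork(tree, fork_id(e$node)))
  names(fp) <- vapply(forks, function(e) fork_id(e$node), "")
  zones <- compute_zones(tree)

  mirrored <- tree$side == "right"
  sm <- arc_mod(skull_marks, 360)  # skull marks are given in left convention

  structure(list(branching_directions = dirs,
                 fork_positions = fp,
                 zones = zones,
                 hierarchy = hierarchy_string(tree),
                 skull_marks = sm,
                 side = "left", mirrored = mirrored),
            class = "burr_diagram")
}

#' @export
print.burr_diagram <- function(x, ...) {
  cat("burr diagram (left-antler convention",
      if (x$mirrored) ", mirrored from right" else "", "):\n", sep = "")
  cat("  hierarchy:", x$hierarchy, "\n")
  if (length(x$branching_directions)) {
    cat("  branching directions (deg):\n")
    for (nm in names(x$branching_directions))
      cat(sprintf("    %-5s %7.2f\n", nm, x$branching_directions[nm]))
  }
  cat("  zones:", nrow(x$zones), " forks:", length(x$fork_positions), "\n")
  invisible(x)
}

#' Mirror an antler left/right
#'
#' Flips every arc position across the SR axis and swaps fork-child
#' ownership so the mirrored tree projects to the mirror image diagram.
#'
#' @param tree A `tine_tree`.
#' @return The mirrored `tine_tree` (opposite `side`).
#' @export
mirror_antler <- function(tree) {
  C <- tree$circumference
  flip <- function(p) arc_mod(C - p, C)
  walk <- function(node) {
    if (length(node$children) == 2L) {
      f <- node$fork
      node$fork <- list(ridge = flip(f$ridge), boundary = flip(f$boundary),
                        child_ridge = rev(vapply(f$child_ridge, flip, 0)))
      node$children <- lapply(rev(node$children), walk)
    }
    node
  }
  tine_tree(walk(tree$root), circumference = C,
            side = if (tree$side == "left") "right" else "left")
}

#' Splice out an overlapping proximal tine
#'
#' Removes a terminal tine and its fork from the tree — predicting the form
#' the same antler would take had that tine never grown — while baking the
#' fork's proration into the surviving coordinates: every arc position
#' stored above the deleted fork that falls on the deleted tine's side is
#' carried across by [remap_across_tine()]. Under the groove-consistency
#' model this leaves every projected burr position unchanged, which is the
#' stated purpose of the proration.
#'
#' @param tree A `tine_tree`.
#' @param tine Code of a terminal element whose sibling subtree replaces
#'   the fork.
#' @return A `tine_tree` without `tine`.
#' @export
delete_proximal_tine <- function(tree, tine) {
  C <- tree$circumference
  idx <- index_tine_tree(tree)
  hit <- which(names(idx) == tine)
  if (!length(hit)) stop("element absent from tree: ", tine)
  entry <- idx[[hit[1L]]]
  if (length(entry$node$children))
    stop("can only delete a terminal tine")
  if (!length(entry$ancestors))
    stop("cannot delete the root segment")
  birth <- entry$ancestors[[length(entry$ancestors)]]
  fk <- birth$node$fork
  sib_which <- 3L - birth$which
  sib_arc <- child_arc(fk, birth$which, C)  # arc of the deleted tine

  remap_if_covered <- function(p) {
    if (in_arc(p, sib_arc[1L], sib_arc[2L], C) &&
        !isTRUE(all.equal(arc_mod(p - sib_arc[1L], C), 0)))
      remap_across_tine(p, fk$ridge, fk$boundary, C)
    else p
  }
  rewrite <- function(node) {
    if (length(node$children) == 2L) {
      f <- node$fork
      node$fork <- list(ridge = remap_if_covered(f$ridge),
                        boundary = remap_if_covered(f$boundary),
                        child_ridge = vapply(f$child_ridge, function(cr) {
                          arc_mod(remap_if_covered(opposite_point(cr, C)) -
                                    C / 2, C)
                        }, 0))
      node$children <- lapply(node$children, rewrite)
    }
    node
  }
  replacement <- rewrite(birth$node$children[[sib_which]])

  splice <- function(node) {
    if (identical(fork_id(node), fork_id(birth$node))) return(replacement)
    if (length(node$children) == 2L)
      node$children <- lapply(node$children, splice)
    node
  }
  new_root <- splice(tree$root)
  tine_tree(new_root, circumference = C, side = tree$side)
}
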