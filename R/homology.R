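#' Classify an antler element by its length ratio
#'
#' Elements whose length exceeds twice the basal diameter are tines or
#' beams (not conceptually distinguished: a tine becomes a beam when its
#' top bifurcates); shorter elements are processes. The boundary is strict:
#' exactly twice the diameter is a process.
#'
#' @param length,basal_diameter Positive lengths (same units).
#' @return `"tine_or_beam"` or `"process"` (vectorised).
#' @export
#' @examples
#' classify_category(50, 20)  # tine_or_beam
#' classify_category(40, 20)  # process ("more than twice" is strict)
classify_category <- function(length, basal_diameter) {
  if (any(length <= 0) || any(basal_diameter <= 0))
    stop("length and basal diameter must be positive")
  ifelse(length > 2 * basal_diameter, "tine_or_beam", "process")
}

## all reference marks of a diagram, as named angles; the lateral/medial
## fork traces get ":lat"/":med" suffixes
diagram_marks <- function(diagram) {
  marks <- c(diagram$skull_marks, diagram$branching_directions)
  for (nm in names(diagram$fork_positions)) {
    fp <- diagram$fork_positions[[nm]]
    marks[paste0("fork:", nm, ":lat")] <- fp[["lateral"]]
    marks[paste0("fork:", nm, ":med")] <- fp[["medial"]]
  }
  marks
}

## merge marks into coincidence groups (circular single-linkage within
## `tol` degrees) and return groups in cyclic order anchored at the group
## containing `anchor`
cyclic_groups <- function(marks, tol, anchor = "SR") {
  ord <- order(marks, names(marks))
  ang <- marks[ord]
  nms <- names(marks)[ord]
  n <- length(ang)
  if (n == 0L) return(list())
  # group split points: gaps > tol (circular)
  gap_next <- c(diff(ang), ang[1L] + 360 - ang[n])
  grp <- integer(n)
  g <- 1L
  for (i in seq_len(n)) {
    grp[i] <- g
    if (gap_next[i] > tol) g <- g + 1L
  }
  if (n > 1L && gap_next[n] <= tol && max(grp) > 1L)
    grp[grp == max(grp)] <- 1L   # wrap-around merge
  groups <- split(nms, grp)
  groups <- lapply(groups, sort)
  # order groups by their first member's angle
  first_ang <- vapply(split(ang, grp), min, 0)
  groups <- groups[order(first_ang)]
  i0 <- which(vapply(groups, function(g) anchor %in% g, TRUE))
  if (length(i0) == 1L && i0 != 1L)
    groups <- c(groups[i0:length(groups)], groups[seq_len(i0 - 1L)])
  unname(groups)
}

## human-readable ordinal predicate for A relative to B given their angles
ordinal_predicate <- function(a, b, tol) {
  d <- arc_signed(a, b, 360)
  if (abs(d) <= tol) return("coincides_with")
  sector <- (floor(arc_mod(b + 45, 360) / 90) %% 4) + 1  # 1=anterior,2=lateral,3=posterior,4=medial
  pos <- d > 0
  switch(sector,
         if (pos) "lateral_to" else "medial_to",       # near SR (anterior)
         if (pos) "posterior_to" else "anterior_to",   # near TR (lateral)
         if (pos) "medial_to" else "lateral_to",       # near BN (posterior)
         if (pos) "anterior_to" else "posterior_to")   # medial side
}

#' Extract the diagram signature of an element
#'
#' The symbolic description the homology comparison uses: the cyclic
#' positional order of the element's branching direction among all
#' reference marks (skull indices, other branching directions, fork
#' traces), with marks closer than the coincidence tolerance merged into
#' one group; the element's branching hierarchy depth (fork count from the
#' antler base); and its fork partner. Ordinal relations are reported as
#' readable predicates (lateral/medial/anterior/posterior of each
#' landmark); matching uses the rotation-invariant cyclic order.
#'
#' @param diagram A `burr_diagram`.
#' @param element Element code present in the diagram.
#' @param tolerance Coincidence tolerance in degrees (default 5): marks
#'   within it count as at the same position.
#' @return An object of class `element_signature`: list with `element`,
#'   `depth`, `partner`, `order` (list of coincidence groups in cyclic
#'   order anchored at SR; the element itself appears as `"self"`, its
#'   partner as `"partner"`), `relations` (data.frame of predicates) and
#'   `tolerance`.
#' @export
extract_signature <- function(diagram, element, tolerance = 5) {
  stopifnot(inherits(diagram, "burr_diagram"))
  if (!element %in% names(diagram$branching_directions))
    stop("element absent from diagram: ", element)

  # depth & partner from the hierarchy parenthesisation
  hp <- hierarchy_partner(diagram$hierarchy, element)

  marks <- diagram_marks(diagram)
  a <- marks[[element]]
  others <- marks[names(marks) != element]
  relations <- data.frame(
    subject = element,
    predicate = vapply(names(others),
                       function(nm) ordinal_predicate(a, others[[nm]],
                                                      tolerance), ""),
    object = names(others), stringsAsFactors = FALSE, row.names = NULL)

  # relabel self and partner so signatures compare across species
  nm2 <- names(marks)
  nm2[nm2 == element] <- "self"
  if (!is.na(hp$partner)) nm2[nm2 == hp$partner] <- "partner"
  marks2 <- stats::setNames(unname(marks), nm2)

  structure(list(element = element, depth = hp$depth, partner = hp$partner,
                 order = cyclic_groups(marks2, tolerance),
                 relations = relations, tolerance = tolerance),
            class = "element_signature")
}

## depth (fork count from base) and fork partner of an element, parsed from
## the hierarchy string
hierarchy_partner <- function(hierarchy, element) {
  tokens <- strsplit(gsub("([(),])", " \\1 ", hierarchy), "\\s+")[[1]]
  tokens <- tokens[tokens != ""]
  depth <- 0L; found_depth <- NA_integer_
  stack <- list()  # per open fork: codes of completed child subtrees
  top_code <- function(sub) sub$code
  cur <- NULL
  # recursive descent parse
  pos <- 1L
  parse_node <- function(d) {
    if (tokens[pos] == "(") {
      pos <<- pos + 1L
      left <- parse_node(d + 1L)
      stopifnot(tokens[pos] == ",")
      pos <<- pos + 1L
      right <- parse_node(d + 1L)
      stopifnot(tokens[pos] == ")")
      pos <<- pos + 1L
      code <- NA_character_
      if (pos <= length(tokens) && !tokens[pos] %in% c("(", ")", ",")) {
        code <- tokens[pos]; pos <<- pos + 1L
      }
      if (!is.na(code) && code == element) found_depth <<- d
      list(code = code, left = left, right = right, depth = d)
    } else {
      code <- tokens[pos]; pos <<- pos + 1L
      if (code == element) found_depth <<- d
      list(code = code, left = NULL, right = NULL, depth = d)
    }
  }
  root <- parse_node(0L)
  # partner: the sibling subtree's code at the element's fork
  partner <- NA_character_
  walk <- function(nd) {
    if (is.null(nd$left)) return(invisible(NULL))
    lc <- nd$left$code; rc <- nd$right$code
    if (identical(lc, element)) partner <<- rc
    if (identical(rc, element)) partner <<- lc
    walk(nd$left); walk(nd$right)
  }
  walk(root)
  if (is.na(found_depth))
    stop("element not in hierarchy: ", element)
  list(depth = found_depth, partner = partner)
}

#' @export
print.element_signature <- function(x, ...) {
  cat("signature of", x$element, "- depth", x$depth,
      "partner", x$partner, "\n")
  cat("  cyclic order:",
      paste(vapply(x$order, function(g) paste(g, collapse = "="), ""),
            collapse = " < "), "\n")
  invisible(x)
}

#' Compare two element signatures for homology
#'
#' Two elements are homologous when they occupy the same position on the
#' diagram: the cyclic positional order of their branching direction
#' relative to all reference marks both diagrams share, their branching
#' hierarchy depth, and their fork partner all agree. Otherwise the
#' violated order relations are reported.
#'
#' @param sig_a,sig_b `element_signature`s extracted with the same
#'   tolerance.
#' @return A list with `homologous` (logical) and `violations` (character
#'   vector describing each disagreement).
#' @export
match_elements <- function(sig_a, sig_b) {
  stopifnot(inherits(sig_a, "element_signature"),
            inherits(sig_b, "element_signature"))
  if (!isTRUE(all.equal(sig_a$tolerance, sig_b$tolerance)))
    warning("signatures extracted with different tolerances")
  violations <- character(0)
  if (sig_a$depth != sig_b$depth)
    violations <- c(violations,
                    sprintf("hierarchy depth %d vs %d", sig_a$depth,
                            sig_b$depth))
  shared <- intersect(unlist(sig_a$order), unlist(sig_b$order))
  ra <- restrict_order(sig_a$order, shared)
  rb <- restrict_order(sig_b$order, shared)
  if (!identical(canonical_cycle(ra), canonical_cycle(rb))) {
    violations <- c(violations, order_violations(ra, rb))
  }
  list(homologous = length(violations) == 0L, violations = violations)
}

restrict_order <- function(groups, keep) {
  out <- lapply(groups, function(g) intersect(g, keep))
  out[vapply(out, length, 0L) > 0L]
}

## canonical string for a cyclic sequence of groups: rotate so the group
## containing SR (or the lexicographically smallest) comes first
canonical_cycle <- function(groups) {
  if (!length(groups)) return("")
  keys <- vapply(groups, function(g) paste(g, collapse = "="), "")
  i0 <- which(vapply(groups, function(g) "SR" %in% g, TRUE))
  if (!length(i0)) i0 <- which.min(keys)
  i0 <- i0[1L]
  paste(keys[c(i0:length(keys), seq_len(i0 - 1L))], collapse = " < ")
}

## describe which pairwise precedences differ between two restricted orders
order_violations <- function(ra, rb) {
  pos_of <- function(groups) {
    lab <- unlist(groups)
    grp <- rep(seq_along(groups), vapply(groups, length, 0L))
    stats::setNames(grp, lab)
  }
  pa <- pos_of(ra); pb <- pos_of(rb)
  lab <- intersect(names(pa), names(pb))
  viol <- character(0)
  # anchor at SR for a linear reading of the cycle
  for (i in seq_along(lab)) for (j in seq_along(lab)) {
    if (i >= j) next
    x <- lab[i]; y <- lab[j]
    rel_a <- sign(pa[x] - pa[y]); rel_b <- sign(pb[x] - pb[y])
    if (rel_a != rel_b)
      viol <- c(viol, sprintf("order of %s and %s differs", x, y))
  }
  if (!length(viol)) viol <- "cyclic order differs"
  viol
}

#' Consensus signature of a species
#'
#' The species' canonical diagram signature: a majority consensus of the
#' positional orders over that species' specimen signatures, ties broken
#' toward the signature carrying the largest weight (sample size).
#'
#' @param sigs List of `element_signature`s of the same element.
#' @param weights Numeric weights (e.g. specimen counts); default 1 each.
#' @return An `element_signature` whose order is the consensus.
#' @export
canonical_signature <- function(sigs, weights = rep(1, length(sigs))) {
  stopifnot(length(sigs) >= 1L, length(weights) == length(sigs))
  if (length(sigs) == 1L) return(sigs[[1L]])
  # mean weighted rank per label, anchored at SR
  ranks <- list()
  for (k in seq_along(sigs)) {
    groups <- sigs[[k]]$order
    lab <- unlist(groups)
    r <- rep(seq_along(groups), vapply(groups, length, 0L))
    for (i in seq_along(lab)) {
      ranks[[lab[i]]] <- c(ranks[[lab[i]]], r[i] * weights[k])
    }
  }
  wsum <- vapply(names(ranks), function(nm) sum(ranks[[nm]]), 0)
  cnt <- vapply(names(ranks), function(nm) length(ranks[[nm]]), 0L)
  mean_rank <- wsum / cnt
  # tie-break: nudge by the order of the largest-weight signature
  big <- sigs[[which.max(weights)]]
  big_rank <- stats::setNames(
    rep(seq_along(big$order), vapply(big$order, length, 0L)),
    unlist(big$order))
  nudge <- big_rank[names(mean_rank)]
  nudge[is.na(nudge)] <- 0
  key <- mean_rank + 1e-9 * nudge
  ord <- sort(key)
  # labels sharing a consensus rank stay one coincidence group
  out <- sigs[[which.max(weights)]]
  out$order <- unname(lapply(split(names(ord),
                                   cumsum(c(1, diff(ord) > 1e-7))), sort))
  out
}
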