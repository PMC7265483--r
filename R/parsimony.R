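#' Dollo parsimony for element presence on a fixed rooted tree
#'
#' Reconstructs presence/absence of one antler element under the constraint
#' that the element is gained exactly once and may be lost any number of
#' times. The gain is placed on the stem edge of the most recent common
#' ancestor (MRCA) of all present tips; an internal node is present iff it
#' lies inside the MRCA clade and its subtree contains at least one present
#' tip; losses are the stem edges of the maximal all-absent subtrees inside
#' the present region. This placement attains the minimum number of losses
#' achievable with a single gain, and the minimal loss set is unique.
#'
#' Edges are identified by their child node id (the stem edge of node `v`
#' is "edge `v`"); a gain at the root node means the character was present
#' in the common ancestor of the whole tree.
#'
#' @param tree A rooted binary `phylo`.
#' @param tip_present Logical (or 0/1) vector named by tip label.
#' @return A list with `presence` (logical per node id), `gain_edge`
#'   (child node id of the gain edge, or `NA` if no tip is present),
#'   `loss_edges` (integer child node ids) and `n_losses`.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' dollo_presence(tr, c(A = 1, B = 0, C = 1, D = 0))
dollo_presence <- function(tree, tip_present) {
  check_rooted_binary(tree)
  tips <- tree$tip.label
  if (!all(tips %in% names(tip_present)))
    stop("unlabelled leaf (missing tip state): ",
         paste(setdiff(tips, names(tip_present)), collapse = ", "))
  x <- as.logical(tip_present[tips])
  if (anyNA(x)) stop("tip presence contains NA")

  n <- n_nodes(tree)
  ntip <- length(tips)
  ch <- children_list(tree)

  has_present <- logical(n)      # subtree contains a present tip
  has_present[seq_len(ntip)] <- x
  for (v in postorder_ids(tree)) {
    if (v > ntip) has_present[v] <- any(has_present[ch[[v]]])
  }

  presence <- logical(n)
  if (!any(x)) {
    return(list(presence = presence, gain_edge = NA_integer_,
                loss_edges = integer(0), n_losses = 0L))
  }
  m <- mrca_node(tree, which(x))
  # present region: descendants-or-self of the MRCA whose subtree holds a
  # present tip (forced under a single gain on the MRCA stem)
  in_clade <- logical(n)
  in_clade[m] <- TRUE
  for (v in preorder_ids(tree)) {
    if (in_clade[v]) for (c in ch[[v]]) in_clade[c] <- TRUE
  }
  presence <- in_clade & has_present
  loss_edges <- integer(0)
  par <- parent_vec(tree)
  for (v in seq_len(n)) {
    if (in_clade[v] && !has_present[v] &&
        !is.na(par[v]) && presence[par[v]])
      loss_edges <- c(loss_edges, v)
  }
  list(presence = presence, gain_edge = m,
       loss_edges = sort(loss_edges), n_losses = length(loss_edges))
}

#' ACCTRAN refinement of frequency grades on the present subtree
#'
#' Given the subtree on which an element is present (from
#' [dollo_presence()]), assigns each present node a grade in \{1, 2\}
#' (1 = observed in under 80\% of the species' adult antlers,
#' 2 = in 80\% or more) by a Fitch up-pass followed by an
#' accelerated-transformation (ACCTRAN) down-pass: a node takes its
#' parent's final grade whenever that grade is in its preliminary set,
#' otherwise its own forced grade, which places grade changes as close to
#' the subtree root as the minimum-change solutions allow. Ambiguity at the
#' subtree root resolves to grade 2 (a newly gained adaptive tine is
#' presumed to sweep through the population immediately after the gain).
#'
#' @param tree A rooted binary `phylo`.
#' @param presence Logical per node id, as returned by [dollo_presence()];
#'   absent tips are pruned (their grade is undefined).
#' @param tip_grades Numeric vector of grades (1 or 2) named by tip label;
#'   needed for every present tip.
#' @param subtree_root Node id of the gain point (defaults to the highest
#'   present node).
#' @return A list with `grades` (numeric per node id, `NA` off the present
#'   subtree), `change_edges` (child node ids of edges with a 1<->2
#'   change), `n_changes`, and `root_grade`.
#' @export
acctran_refine <- function(tree, presence, tip_grades,
                           subtree_root = NULL) {
  check_rooted_binary(tree)
  n <- n_nodes(tree)
  ntip <- length(tree$tip.label)
  ch <- children_list(tree)
  par <- parent_vec(tree)
  grades <- rep(NA_real_, n)
  if (!any(presence))
    return(list(grades = grades, change_edges = integer(0),
                n_changes = 0L, root_grade = NA_real_))
  if (is.null(subtree_root)) {
    pres_nodes <- which(presence)
    subtree_root <- pres_nodes[which.min(node_depths(tree)[pres_nodes])]
  }

  g <- tip_grades[tree$tip.label]
  present_tips <- which(presence[seq_len(ntip)])
  if (anyNA(g[present_tips]))
    stop("ungraded present tip: ",
         paste(tree$tip.label[present_tips[is.na(g[present_tips])]],
               collapse = ", "))
  if (!all(g[present_tips] %in% c(1, 2)))
    stop("grades must be 1 or 2")

  # Fitch up-pass over the induced present subtree; sets coded as
  # 1 = {1}, 2 = {2}, 3 = {1,2}
  prelim <- rep(NA_integer_, n)
  for (v in postorder_ids(tree)) {
    if (!presence[v]) next
    if (v <= ntip) {
      prelim[v] <- as.integer(g[v])
    } else {
      kids <- ch[[v]][presence[ch[[v]]]]
      if (length(kids) == 0L) {
        stop("present internal node with no present child")
      } else if (length(kids) == 1L) {
        prelim[v] <- prelim[kids]
      } else {
        a <- prelim[kids[1L]]; b <- prelim[kids[2L]]
        inter <- bitwAnd(a, b)
        prelim[v] <- if (inter > 0L) inter else bitwOr(a, b)
      }
    }
  }

  # ACCTRAN down-pass
  final <- rep(NA_real_, n)
  final[subtree_root] <- if (prelim[subtree_root] == 3L) 2
                         else as.numeric(prelim[subtree_root])
  change_edges <- integer(0)
  for (v in preorder_ids(tree)) {
    if (!presence[v] || v == subtree_root) next
    p <- par[v]
    if (is.na(final[p])) next   # outside the subtree rooted at the gain
    fp <- as.integer(final[p])
    final[v] <- if (bitwAnd(prelim[v], fp) > 0L) final[p]
                else as.numeric(prelim[v])  # forced singleton
    if (final[v] != final[p]) change_edges <- c(change_edges, v)
  }
  list(grades = final, change_edges = sort(change_edges),
       n_changes = length(change_edges),
       root_grade = final[subtree_root])
}

#' Reconstruct one element's ancestral character states
#'
#' The two-layer hybrid scheme: presence (state 0 vs \{1, 2\}) by Dollo
#' parsimony (single gain, unlimited losses), then within-species frequency
#' grades (1 vs 2) on the present subtree by Fitch parsimony with ACCTRAN
#' resolution, absent tips pruned beforehand.
#'
#' @param tree A rooted binary `phylo`.
#' @param tip_states Numeric vector of states in \{0, 1, 2\} named by tip
#'   label (must cover every leaf).
#' @param element Optional element code carried through to the result.
#' @return An object of class `reconstruction`: list with `element`,
#'   `node_states` (numeric vector named by node name, states in
#'   \{0, 1, 2\}), `gain_edge` (node name or `NA`), `loss_edges`,
#'   `grade_change_edges` (node names), and the underlying id vectors.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "(((A,B),C),(D,E));")
#' reconstruct_character(tr, c(A = 2, B = 2, C = 0, D = 1, E = 0), "B")
reconstruct_character <- function(tree, tip_states, element = NA_character_) {
  check_rooted_binary(tree)
  tips <- tree$tip.label
  if (!all(tips %in% names(tip_states)))
    stop("tip states must cover all leaves; missing: ",
         paste(setdiff(tips, names(tip_states)), collapse = ", "))
  s <- tip_states[tips]
  if (!all(s %in% c(0, 1, 2))) stop("tip states must be 0, 1 or 2")

  dollo <- dollo_presence(tree, stats::setNames(s > 0, tips))
  grades <- acctran_refine(tree, dollo$presence,
                           stats::setNames(as.numeric(s), tips),
                           subtree_root = if (is.na(dollo$gain_edge)) NULL
                                          else dollo$gain_edge)
  node_states <- ifelse(dollo$presence, grades$grades, 0)
  nm <- node_names(tree)
  structure(list(
    element = element,
    node_states = stats::setNames(node_states, nm),
    gain_edge = if (is.na(dollo$gain_edge)) NA_character_
                else nm[dollo$gain_edge],
    loss_edges = nm[dollo$loss_edges],
    grade_change_edges = nm[grades$change_edges],
    gain_edge_id = dollo$gain_edge,
    loss_edge_ids = dollo$loss_edges,
    grade_change_edge_ids = grades$change_edges,
    n_losses = dollo$n_losses,
    n_grade_changes = grades$n_changes,
    tree = tree), class = "reconstruction")
}

#' @export
print.reconstruction <- function(x, ...) {
  cat("reconstruction of element", x$element, "\n")
  if (is.na(x$gain_edge)) {
    cat("  absent everywhere (no gain)\n")
  } else {
    cat("  gain on stem edge of:", x$gain_edge, "\n")
    cat("  losses (", x$n_losses, "):",
        paste(x$loss_edges, collapse = ", "), "\n")
    cat("  grade changes (", x$n_grade_changes, "):",
        paste(x$grade_change_edges, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read tip states back from a reconstruction
#'
#' @param recon A `reconstruction`.
#' @return Named numeric vector of tip states.
#' @export
tip_states_of <- function(recon) {
  tips <- recon$tree$tip.label
  recon$node_states[tips]
}

#' Assemble the ancestral antler at one node
#'
#' An element is part of the node's antler iff its reconstructed state
#' there is above 0 and all its structurally required elements are present
#' too; requirement violations are reported, never silently repaired. The
#' skeleton is assembled from the registry's attachment topology (each
#' element attaches to its direct requirement, or to the antler base).
#'
#' @param node A node id, or a node/clade label resolvable by
#'   [clade_node()].
#' @param reconstructions List of `reconstruction` objects (one per
#'   element), e.g. from [reconstruct_all()].
#' @param registry An `antler_registry`.
#' @return An object of class `ancestral_antler`: list with `node` (name),
#'   `states` (named numeric, elements with state > 0), `elements`
#'   (character vector of structurally consistent present elements),
#'   `violations` (data.frame of dependency violations), `skeleton`
#'   (named list: element -> attachment parent code or "base") and
#'   `points` (the point count).
#' @export
assemble_ancestral_antler <- function(node, reconstructions, registry) {
  stopifnot(length(reconstructions) >= 1L)
  tree <- reconstructions[[1L]]$tree
  if (is.character(node)) node <- clade_node(tree, node)
  nm <- node_names(tree)[node]
  states <- vapply(reconstructions, function(r) unname(r$node_states[node]), 0)
  names(states) <- vapply(reconstructions, function(r) r$element, "")
  present <- names(states)[states > 0]

  viol <- list()
  for (code in present) {
    req <- registry$elements$requires[[match(code, registry$elements$code)]]
    missing <- setdiff(req, present)
    if (length(missing))
      viol[[length(viol) + 1L]] <- data.frame(
        element = code, missing = paste(missing, collapse = ";"),
        stringsAsFactors = FALSE)
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(element = character(0), missing = character(0))
  ok <- setdiff(present, violations$element)

  skeleton <- lapply(ok, function(code) {
    req <- registry$elements$requires[[match(code, registry$elements$code)]]
    att <- intersect(req, ok)
    if (length(att)) att[1L] else "base"
  })
  names(skeleton) <- ok

  antler <- structure(list(node = nm, states = states[states > 0],
                           elements = ok, violations = violations,
                           skeleton = skeleton, registry = registry,
                           points = NA_integer_),
                      class = "ancestral_antler")
  antler$points <- count_points(antler)
  antler
}

#' Count the points of an assembled antler
#'
#' A "point" is a terminal tip of a tine or beam in the skeleton: a present
#' tine/beam element with no present tine/beam attached distally to it.
#' Processes are excluded both as points and as point-bearing tips (a brow
#' process does not add a point).
#'
#' @param antler An `ancestral_antler`.
#' @return Non-negative integer point count.
#' @export
#' @examples
#' # a two-element antler (brow tine + lower beam) counts 2 points
count_points <- function(antler) {
  stopifnot(inherits(antler, "ancestral_antler"))
  el <- antler$registry$elements
  codes <- antler$elements
  if (!length(codes)) return(0L)
  cat_of <- stats::setNames(el$category, el$code)
  tb <- codes[cat_of[codes] %in% c("tine", "beam")]
  attach_parent <- unlist(antler$skeleton[tb])
  sum(vapply(tb, function(code) {
    kids <- tb[attach_parent[tb] == code]
    length(kids) == 0L
  }, TRUE))
}

#' @export
print.ancestral_antler <- function(x, ...) {
  cat("ancestral antler at node", x$node, "—", x$points, "point(s)\n")
  if (length(x$elements)) {
    el <- x$registry$elements
    nm <- stats::setNames(el$name, el$code)
    for (code in x$elements)
      cat(sprintf("  %-4s %s (state %g)\n", code, nm[code], x$states[code]))
  } else cat("  (no elements)\n")
  if (nrow(x$violations))
    cat("  dependency violations:",
        paste(x$violations$element, collapse = ", "), "\n")
  invisible(x)
}

#' Reconstruct every element of a character state matrix
#'
#' @param tree A rooted binary `phylo` whose tip labels (underscores for
#'   spaces) match the matrix rows.
#' @param states A species-by-element numeric matrix of states in
#'   \{0, 1, 2\} (rows named by species).
#' @return Named list of `reconstruction` objects, one per column.
#' @export
reconstruct_all <- function(tree, states) {
  check_rooted_binary(tree)
  rn <- gsub(" ", "_", rownames(states))
  if (!all(tree$tip.label %in% rn))
    stop("state matrix does not cover all tree leaves: ",
         paste(setdiff(tree$tip.label, rn), collapse = ", "))
  out <- lapply(colnames(states), function(code) {
    reconstruct_character(tree,
                          stats::setNames(states[, code], rn), code)
  })
  stats::setNames(out, colnames(states))
}
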