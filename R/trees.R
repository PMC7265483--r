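## Internal helpers over ape "phylo" trees. Trees must be rooted and binary
## (the reconstruction is defined on the fixed rooted topology only).

check_rooted_binary <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!ape::is.binary(tree)) stop("tree must be binary")
  invisible(tree)
}

n_nodes <- function(tree) length(tree$tip.label) + tree$Nnode

root_node <- function(tree) length(tree$tip.label) + 1L

## children[[node]] = integer vector of child node ids (empty for tips)
children_list <- function(tree) {
  n <- n_nodes(tree)
  ch <- vector("list", n)
  for (i in seq_len(n)) ch[[i]] <- integer(0)
  e <- tree$edge
  for (i in seq_len(nrow(e))) ch[[e[i, 1L]]] <- c(ch[[e[i, 1L]]], e[i, 2L])
  ch
}

parent_vec <- function(tree) {
  p <- rep(NA_integer_, n_nodes(tree))
  p[tree$edge[, 2L]] <- tree$edge[, 1L]
  p
}

## node ids in postorder (children before parents)
postorder_ids <- function(tree) {
  ch <- children_list(tree)
  out <- integer(0)
  walk <- function(v) {
    for (c in ch[[v]]) walk(c)
    out[[length(out) + 1L]] <<- v
  }
  walk(root_node(tree))
  out
}

preorder_ids <- function(tree) rev(postorder_ids(tree))

#' Human-readable node names for a tree
#'
#' Tips take their tip label; internal nodes take their node label when one
#' is present, otherwise `N<id>`.
#'
#' @param tree A rooted `phylo`.
#' @return Character vector indexed by node id.
#' @export
node_names <- function(tree) {
  ntip <- length(tree$tip.label)
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", tree$Nnode)
  internal <- ifelse(is.na(lab) | lab == "",
                     paste0("N", ntip + seq_len(tree$Nnode)), lab)
  c(tree$tip.label, internal)
}

#' Find a node by its clade label or tip label
#'
#' @param tree A rooted `phylo` with node labels.
#' @param label A tip label or internal node label.
#' @return The integer node id.
#' @export
clade_node <- function(tree, label) {
  nm <- node_names(tree)
  hit <- which(nm == label)
  if (!length(hit)) stop("no node labelled '", label, "' in tree")
  hit[1L]
}

## MRCA of a set of tip ids (>= 1); for a single tip, the tip itself.
mrca_node <- function(tree, tips) {
  stopifnot(length(tips) >= 1L)
  if (length(tips) == 1L) return(as.integer(tips))
  par <- parent_vec(tree)
  anc <- function(v) {
    out <- v
    while (!is.na(par[v])) { v <- par[v]; out <- c(out, v) }
    out
  }
  common <- Reduce(intersect, lapply(tips, anc))
  common[1L]  # ancestors listed bottom-up, first common is the MRCA
}

## tip ids (integer) under each node
tips_under <- function(tree) {
  ntip <- length(tree$tip.label)
  ch <- children_list(tree)
  res <- vector("list", n_nodes(tree))
  for (v in postorder_ids(tree)) {
    res[[v]] <- if (v <= ntip) v else unlist(res[ch[[v]]])
  }
  res
}

## depth of each node in edges from the root (root = 0)
node_depths <- function(tree) {
  d <- rep(NA_real_, n_nodes(tree))
  d[root_node(tree)] <- 0
  par <- parent_vec(tree)
  for (v in preorder_ids(tree)) {
    if (!is.na(par[v])) d[v] <- d[par[v]] + 1
  }
  d
}
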