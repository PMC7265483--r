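# Exhaustive enumeration of rooted binary trees (as nested lists) and
# brute-force parsimony oracles, independent of the package's algorithms.

# all rooted binary labelled topologies on the given leaf labels
all_labeled_trees <- function(labels) {
  stopifnot(length(labels) >= 1L)
  if (length(labels) == 1L) return(list(labels[[1L]]))
  insert_everywhere <- function(t, leaf) {
    res <- list(list(t, leaf))          # new root above the old one
    if (is.list(t)) {
      for (i in 1:2) {
        for (s in insert_everywhere(t[[i]], leaf)) {
          t2 <- t
          t2[[i]] <- s
          res <- c(res, list(t2))
        }
      }
    }
    res
  }
  out <- all_labeled_trees(labels[-length(labels)])
  leaf <- labels[[length(labels)]]
  unlist(lapply(out, insert_everywhere, leaf = leaf), recursive = FALSE)
}

shape_of <- function(t) {
  if (!is.list(t)) return("*")
  kids <- sort(c(shape_of(t[[1L]]), shape_of(t[[2L]])))
  paste0("(", kids[1L], ",", kids[2L], ")")
}

# one labelled representative per tree shape
all_tree_shapes <- function(labels) {
  trees <- all_labeled_trees(labels)
  trees[!duplicated(vapply(trees, shape_of, ""))]
}

nested_to_newick <- function(t) {
  render <- function(x) {
    if (!is.list(x)) return(x)
    paste0("(", render(x[[1L]]), ",", render(x[[2L]]), ")")
  }
  paste0(render(t), ";")
}

nested_to_phylo <- function(t) ape::read.tree(text = nested_to_newick(t))

# brute force over all internal-node presence assignments: minimum losses
# attainable by any single-gain history consistent with the tip states
dollo_oracle_min_losses <- function(tree, tip01) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  e <- tree$edge
  internal <- (ntip + 1L):nn
  k <- length(internal)
  best <- Inf
  for (mask in 0:(2^k - 1L)) {
    st <- integer(nn)
    st[seq_len(ntip)] <- tip01
    st[internal] <- bitwAnd(bitwShiftR(mask, seq_len(k) - 1L), 1L)
    gains <- (st[ntip + 1L] == 1L) +
      sum(st[e[, 1L]] == 0L & st[e[, 2L]] == 1L)
    if (gains > 1L) next
    losses <- sum(st[e[, 1L]] == 1L & st[e[, 2L]] == 0L)
    if (losses < best) best <- losses
  }
  best
}

# brute force Fitch: minimum number of state changes over all internal
# assignments for binary states in {1, 2}; also the minimum change-edge
# depth attained by any minimum-change assignment
fitch_oracle <- function(tree, tip_grades) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  e <- tree$edge
  internal <- (ntip + 1L):nn
  k <- length(internal)
  depth <- numeric(nn)
  depth[ntip + 1L] <- 0
  # parent-before-child order for depths
  for (i in seq_len(nrow(e))) depth[e[i, 2L]] <- NA
  repeat {
    done <- TRUE
    for (i in seq_len(nrow(e))) {
      if (is.na(depth[e[i, 2L]]) && !is.na(depth[e[i, 1L]])) {
        depth[e[i, 2L]] <- depth[e[i, 1L]] + 1
        done <- FALSE
      }
    }
    if (done) break
  }
  best <- Inf
  best_min_depth <- Inf
  for (mask in 0:(2^k - 1L)) {
    st <- integer(nn)
    st[seq_len(ntip)] <- tip_grades
    st[internal] <- bitwAnd(bitwShiftR(mask, seq_len(k) - 1L), 1L) + 1L
    chg <- st[e[, 1L]] != st[e[, 2L]]
    nc <- sum(chg)
    if (nc < best) {
      best <- nc
      best_min_depth <- if (nc > 0) min(depth[e[chg, 2L]]) else Inf
    } else if (nc == best && nc > 0) {
      best_min_depth <- min(best_min_depth, min(depth[e[chg, 2L]]))
    }
  }
  list(length = best, min_change_depth = best_min_depth, depth = depth)
}

# every 0/1 assignment over n tips as rows
all_assignments <- function(n, values = c(0L, 1L)) {
  as.matrix(expand.grid(rep(list(values), n)))
}
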