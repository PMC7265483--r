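#' Simulation configuration
#'
#' Bundles the parameters of the trait-history, specimen-sampling and
#' antler-geometry simulators. All randomness flows from the single `seed`;
#' the global RNG state is saved and restored around every simulation.
#'
#' @param seed Integer seed.
#' @param gain_edge Node id or node/tip label of the gain edge's child
#'   (`NULL`: drawn uniformly over all edges plus the root stem).
#' @param loss_probability Per-edge probability that a present element is
#'   lost (default 0.1).
#' @param grade_upgrade_probability Per-edge probability of a 1 -> 2 grade
#'   change where the element is present (default 0.9: a newly gained
#'   adaptive tine sweeps through the population almost immediately).
#' @param grade_downgrade_probability Per-edge probability of 2 -> 1
#'   (default 0.1).
#' @param specimens_per_species Antlers sampled per species (default 20,
#'   the scale of a typical museum series in the packaged sample table).
#' @param frequency_map Sampling frequency of an element in a specimen
#'   given the species' state: defaults 2 -> 0.95, 1 -> 0.3, 0 -> 0.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, gain_edge = NULL,
                       loss_probability = 0.1,
                       grade_upgrade_probability = 0.9,
                       grade_downgrade_probability = 0.1,
                       specimens_per_species = 20L,
                       frequency_map = c("0" = 0, "1" = 0.3, "2" = 0.95)) {
  probs <- c(loss_probability, grade_upgrade_probability,
             grade_downgrade_probability, frequency_map)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (specimens_per_species < 1) stop("specimen count must be positive")
  if (!all(c("0", "1", "2") %in% names(frequency_map)))
    stop("frequency_map needs entries for states 0, 1 and 2")
  structure(list(seed = as.integer(seed), gain_edge = gain_edge,
                 loss_probability = loss_probability,
                 grade_upgrade_probability = grade_upgrade_probability,
                 grade_downgrade_probability = grade_downgrade_probability,
                 specimens_per_species = as.integer(specimens_per_species),
                 frequency_map = frequency_map),
            class = "sim_config")
}

## evaluate `expr` under the config seed, restoring the caller's RNG state
with_sim_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a Dollo-consistent character history
#'
#' Evolves one element down the fixed tree under the assumptions of the
#' reconstruction: the element arises exactly once (state 1 on the gain
#' edge, with the usual immediate chance of sweeping to 2), may be lost on
#' any edge below (and once lost never returns), and its frequency grade
#' wanders between 1 and 2 where it is present.
#'
#' @param tree A rooted binary `phylo`.
#' @param config A [sim_config()]. `config$gain_edge` may be `NA` to force
#'   an all-absent character.
#' @return A list with `node_states` (named by node name), `tip_states`
#'   (named by tip label), `gain_edge` (node id), `loss_edges` (node ids of
#'   realised losses), and `config`.
#' @export
simulate_dollo_character <- function(tree, config = sim_config()) {
  check_rooted_binary(tree)
  n <- n_nodes(tree)
  ntip <- length(tree$tip.label)
  nm <- node_names(tree)
  with_sim_seed(config$seed, {
    ge <- config$gain_edge
    if (is.null(ge)) {
      ge <- sample(n, 1L)  # any node's stem edge, incl. the root stem
    } else if (is.character(ge)) {
      ge <- clade_node(tree, ge)
    } else if (!is.na(ge)) {
      ge <- as.integer(ge)
      if (ge < 1L || ge > n) stop("invalid gain edge id: ", ge)
    }
    states <- rep(0, n)
    loss_edges <- integer(0)
    if (!is.na(ge)) {
      # state arises on the gain edge
      g <- 1
      if (stats::runif(1) < config$grade_upgrade_probability) g <- 2
      states[ge] <- g
      ch <- children_list(tree)
      # preorder below the gain node
      walk <- function(v) {
        for (c in ch[[v]]) {
          if (states[v] == 0) {
            states[c] <<- 0
          } else if (stats::runif(1) < config$loss_probability) {
            states[c] <<- 0
            loss_edges <<- c(loss_edges, c)
          } else if (states[v] == 1) {
            states[c] <<- if (stats::runif(1) <
                              config$grade_upgrade_probability) 2 else 1
          } else {
            states[c] <<- if (stats::runif(1) <
                              config$grade_downgrade_probability) 1 else 2
          }
          walk(c)
        }
      }
      walk(ge)
    }
    list(node_states = stats::setNames(states, nm),
         tip_states = stats::setNames(states[seq_len(ntip)],
                                      tree$tip.label),
         gain_edge = if (is.na(ge)) NA_integer_ else ge,
         loss_edges = loss_edges, config = config)
  })
}

#' Simulate a specimen matrix from species states
#'
#' The inverse of the coding step: each antler carries each element
#' independently with the sampling frequency of the species' state
#' (`config$frequency_map`). Left and right antlers alternate; all rows are
#' adults.
#'
#' @param species_states A species-by-element state matrix in \{0, 1, 2\}
#'   (rows named by species), or a named vector for a single element
#'   (column named `"E1"`).
#' @param config A [sim_config()]; `specimens_per_species` may also be a
#'   named vector.
#' @return A specimen matrix data.frame (see [validate_specimens()]).
#' @export
simulate_specimens <- function(species_states, config = sim_config()) {
  if (is.null(dim(species_states))) {
    species_states <- matrix(species_states, ncol = 1,
                             dimnames = list(names(species_states), "E1"))
  }
  if (!all(species_states %in% 0:2)) stop("states must be 0, 1 or 2")
  nper <- config$specimens_per_species
  sp <- rownames(species_states)
  if (length(nper) == 1L) nper <- stats::setNames(rep(nper, length(sp)), sp)
  with_sim_seed(config$seed, {
    rows <- lapply(sp, function(s) {
      k <- nper[[s]]
      freq <- config$frequency_map[as.character(species_states[s, ])]
      m <- matrix(stats::rbinom(k * ncol(species_states), 1L,
                                rep(freq, each = k)),
                  nrow = k, dimnames = list(NULL,
                                            colnames(species_states)))
      data.frame(specimen_id = sprintf("%s_%03d", gsub(" ", "_", s),
                                       ceiling(seq_len(k) / 2)),
                 species = s,
                 side = rep_len(c("left", "right"), k),
                 age = "adult", m,
                 check.names = FALSE, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate a random synthetic antler
#'
#' Draws a random binary tine tree with positive lengths and diameters and
#' internally consistent fork geometry: zones are allotted by recursive arc
#' subdivision on the burr circle, so the generated antler always builds a
#' valid diagram whose zones partition the circle.
#'
#' @param config A [sim_config()] (only the seed is used).
#' @param max_depth Maximum fork nesting depth (default 3).
#' @param p_branch Probability that a segment forks again at each depth
#'   (default 0.6).
#' @param circumference Shared coordinate circumference (default 360).
#' @param side `"left"` or `"right"`.
#' @return A `tine_tree`.
#' @export
synthetic_antler <- function(config = sim_config(), max_depth = 3,
                             p_branch = 0.6, circumference = 360,
                             side = "left") {
  C <- circumference
  with_sim_seed(config$seed, {
    counter <- 0L
    new_code <- function() {
      counter <<- counter + 1L
      paste0("E", counter)
    }
    rand_in <- function(lo, hi, margin = 0.05) {
      # a point strictly inside the + arc from lo to hi
      span <- arc_mod(hi - lo, C)
      if (span == 0) span <- C
      arc_mod(lo + span * stats::runif(1, margin, 1 - margin), C)
    }
    # build the subtree owning the + arc (lo, hi); returns a tine_node
    build <- function(lo, hi, depth) {
      diameter <- stats::runif(1, 10, 30)
      len <- diameter * stats::runif(1, 2.5, 6)
      span <- arc_mod(hi - lo, C)
      if (span == 0) span <- C
      branch <- depth < max_depth && stats::runif(1) < p_branch &&
        span > C / 36
      if (!branch) {
        dir <- rand_in(lo, hi)
        nd <- tine_node(new_code(), "tine", len, diameter)
        attr(nd, "dir") <- dir
        return(nd)
      }
      # split (lo, hi) into: own-direction arc, child1 arc, child2 arc
      cuts <- sort(stats::runif(3, 0.1, 0.9)) * span
      m1 <- arc_mod(lo + cuts[2L], C)  # fork ridge
      m2 <- arc_mod(lo + cuts[3L], C)  # fork boundary trace
      own_dir <- rand_in(lo, arc_mod(lo + cuts[1L], C))
      c1 <- build(m1, m2, depth + 1L)
      c2 <- build(m2, hi, depth + 1L)
      fork <- list(ridge = m1, boundary = m2,
                   child_ridge = c(arc_mod(attr(c1, "dir") - C / 2, C),
                                   arc_mod(attr(c2, "dir") - C / 2, C)))
      nd <- tine_node(new_code(), "beam", len, diameter,
                      fork = fork, children = list(c1, c2))
      attr(nd, "dir") <- own_dir
      nd
    }
    # the base always forks once (a spike is the depth-0 special case)
    r0 <- stats::runif(1, 0, C)
    span0 <- stats::runif(1, 0.25, 0.75) * C
    b0 <- arc_mod(r0 + span0, C)
    if (max_depth < 1) {
      root <- tine_node("L", "beam", 150, 25)
      return(tine_tree(root, circumference = C, side = side))
    }
    c1 <- build(r0, b0, 1L)
    c2 <- build(b0, r0, 1L)
    fork <- list(ridge = r0, boundary = b0,
                 child_ridge = c(arc_mod(attr(c1, "dir") - C / 2, C),
                                 arc_mod(attr(c2, "dir") - C / 2, C)))
    root <- tine_node("base", "base", 60, 40, fork = fork,
                      children = list(c1, c2))
    tine_tree(root, circumference = C, side = side)
  })
}
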