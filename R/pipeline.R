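#' Run the full reconstruction pipeline
#'
#' Orchestrates the analysis end to end: specimen matrix (or the curated
#' species frequency registry) -> species percentages -> \{0, 1, 2\}
#' character states -> per-element Dollo + ACCTRAN reconstruction on the
#' fixed topology -> ancestral antler assembly and point counts at every
#' named internal node. Deterministic given its inputs.
#'
#' @param specimens Optional specimen matrix data.frame (full pipeline
#'   including the coding step).
#' @param states Optional precoded species-by-element state matrix (skips
#'   coding; overrides `specimens`).
#' @param registry An `antler_registry` (default: the packaged fixtures).
#'   When neither `specimens` nor `states` is given, states are coded from
#'   the registry's curated frequency percentages.
#' @param tree Rooted binary `phylo` (default: the registry topology).
#' @param nodes Nodes at which to assemble ancestral antlers (default: all
#'   labelled internal nodes).
#' @param out_dir Optional output directory; when given, writes
#'   `states.csv`, `states.nex`, `events.csv`, `node_states.json`,
#'   `antlers.json`, `summary.txt` and one SVG diagram per requested node.
#' @param seed Echoed into the report (the pipeline itself draws no random
#'   numbers).
#' @return An object of class `antler_run_report`.
#' @export
#' @examples
#' rep <- run_pipeline()
#' rep$antlers[["Cervidae"]]$points   # 2: brow tine + lower beam
run_pipeline <- function(specimens = NULL, states = NULL,
                         registry = load_registry(),
                         tree = registry$topology,
                         nodes = NULL, out_dir = NULL, seed = NULL) {
  check_rooted_binary(tree)
  diagnostics <- character(0)
  digests <- list()

  if (is.null(states)) {
    if (!is.null(specimens)) {
      pct <- species_percentages(specimens, registry)
      excluded <- attr(pct, "excluded")
      if (length(excluded))
        diagnostics <- c(diagnostics,
                         paste("species excluded from coding (no adults):",
                               paste(excluded, collapse = ", ")))
      states <- code_character_matrix(pct)
      digests$specimens <- digest_of(specimens)
    } else {
      states <- states_from_registry(registry)
      digests$registry <- digest_of(registry$frequencies)
    }
  } else {
    digests$states <- digest_of(unclass(states))
  }
  digests$tree <- digest_of(ape::write.tree(tree))

  if (ncol(states) == 0L)
    warning("no element columns: report will be empty")

  # species absent from the matrix but present on the tree are an error;
  # tree tips use underscores for spaces
  rn <- gsub(" ", "_", rownames(states))
  missing <- setdiff(tree$tip.label, rn)
  if (length(missing))
    stop("species on the tree but not in the matrix: ",
         paste(missing, collapse = ", "))

  recons <- if (ncol(states)) reconstruct_all(tree, states) else list()

  nm <- node_names(tree)
  if (is.null(nodes)) {
    ntip <- length(tree$tip.label)
    internal <- nm[(ntip + 1L):length(nm)]
    nodes <- internal[!grepl("^N\\d+$", internal)]
  }
  antlers <- lapply(nodes, function(nd) {
    if (!length(recons)) {
      structure(list(node = nd, states = numeric(0),
                     elements = character(0),
                     violations = data.frame(element = character(0),
                                             missing = character(0)),
                     skeleton = list(), registry = registry, points = 0L),
                class = "ancestral_antler")
    } else assemble_ancestral_antler(nd, recons, registry)
  })
  names(antlers) <- nodes
  for (a in antlers) {
    if (nrow(a$violations))
      diagnostics <- c(diagnostics,
                       sprintf("dependency violation at %s: %s", a$node,
                               paste(a$violations$element, collapse = ", ")))
  }

  report <- structure(list(states = states, reconstructions = recons,
                           antlers = antlers, diagnostics = diagnostics,
                           digests = digests, seed = seed,
                           tree = tree, registry = registry),
                      class = "antler_run_report")
  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

digest_of <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' @export
print.antler_run_report <- function(x, ...) {
  cat("antler pipeline run:", nrow(x$states), "species x",
      ncol(x$states), "elements\n")
  for (nd in names(x$antlers)) {
    a <- x$antlers[[nd]]
    cat(sprintf("  %-22s %d point(s): %s\n", nd, a$points,
                paste(a$elements, collapse = " ")))
  }
  if (length(x$diagnostics))
    cat("diagnostics:\n", paste(" -", x$diagnostics, collapse = "\n"), "\n")
  invisible(x)
}

#' Edge-event table of a run
#'
#' @param report An `antler_run_report`.
#' @return data.frame with `element`, `event` (gain/loss/grade_change) and
#'   `edge` (name of the edge's child node).
#' @export
event_table <- function(report) {
  rows <- list()
  for (r in report$reconstructions) {
    if (!is.na(r$gain_edge))
      rows[[length(rows) + 1L]] <- data.frame(element = r$element,
                                              event = "gain",
                                              edge = r$gain_edge)
    for (e in r$loss_edges)
      rows[[length(rows) + 1L]] <- data.frame(element = r$element,
                                              event = "loss", edge = e)
    for (e in r$grade_change_edges)
      rows[[length(rows) + 1L]] <- data.frame(element = r$element,
                                              event = "grade_change",
                                              edge = e)
  }
  if (!length(rows))
    return(data.frame(element = character(0), event = character(0),
                      edge = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a run report to disk
#'
#' @param report An `antler_run_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_states_csv(report$states, file.path(out_dir, "states.csv"))
  write_states_nexus(report$states, file.path(out_dir, "states.nex"))
  utils::write.csv(event_table(report), file.path(out_dir, "events.csv"),
                   row.names = FALSE, quote = FALSE)
  node_states <- lapply(report$reconstructions, function(r)
    as.list(r$node_states))
  jsonlite::write_json(node_states, file.path(out_dir, "node_states.json"),
                       auto_unbox = TRUE, digits = NA)
  antlers <- lapply(report$antlers, function(a)
    list(node = a$node, points = a$points, elements = as.list(a$states),
         violations = a$violations$element))
  jsonlite::write_json(antlers, file.path(out_dir, "antlers.json"),
                       auto_unbox = TRUE, digits = NA)
  for (nd in names(report$antlers)) {
    a <- report$antlers[[nd]]
    if (!length(a$elements)) next
    dg <- skeleton_diagram(a)
    if (is.null(dg)) next
    render_diagram(dg, file.path(out_dir, paste0("diagram_", nd, ".svg")))
  }
  summary_lines <- c(
    sprintf("antler pipeline run (seed: %s)",
            if (is.null(report$seed)) "none" else report$seed),
    sprintf("species: %d  elements: %d", nrow(report$states),
            ncol(report$states)),
    "",
    vapply(names(report$antlers), function(nd) {
      a <- report$antlers[[nd]]
      sprintf("%-22s %d point(s): %s", nd, a$points,
              paste(a$elements, collapse = " "))
    }, ""),
    "",
    if (length(report$diagnostics))
      c("diagnostics:", paste(" -", report$diagnostics)) else "no diagnostics",
    "", "input digests:",
    paste(" ", names(report$digests), unlist(report$digests)))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}

#' Schematic burr diagram of an assembled ancestral antler
#'
#' Lays the skeleton's elements out on the burr circle with evenly allotted
#' zones, in depth-first order of the attachment topology — a drawing aid
#' for the reconstructed silhouettes, not measured geometry (no fork marks
#' are drawn).
#'
#' @param antler An `ancestral_antler`.
#' @param skull_marks Skull-index angles for the frame.
#' @return A `burr_diagram`, or `NULL` for an empty antler.
#' @export
skeleton_diagram <- function(antler, skull_marks = default_skull_marks()) {
  codes <- antler$elements
  if (!length(codes)) return(NULL)
  kids_of <- function(code)
    codes[vapply(antler$skeleton[codes], identical, TRUE, y = code)]
  dfs <- character(0)
  walk <- function(code) {
    dfs <<- c(dfs, code)
    for (k in kids_of(code)) walk(k)
  }
  for (k in kids_of("base")) walk(k)
  hier <- local({
    render <- function(code) {
      kids <- kids_of(code)
      if (!length(kids)) return(code)
      paste0("(", paste(vapply(kids, render, ""), collapse = ","), ")",
             code)
    }
    base_kids <- kids_of("base")
    paste0("(", paste(vapply(base_kids, render, ""), collapse = ","), ")")
  })
  k <- length(dfs)
  starts <- 360 * (seq_len(k) - 1L) / k
  ends <- 360 * seq_len(k) / k
  dirs <- stats::setNames((starts + ends) / 2, dfs)
  structure(list(branching_directions = dirs,
                 fork_positions = list(),
                 zones = data.frame(element = dfs, start = starts,
                                    end = ends %% 360,
                                    stringsAsFactors = FALSE),
                 hierarchy = hier,
                 skull_marks = arc_mod(skull_marks, 360),
                 side = "left", mirrored = FALSE),
            class = "burr_diagram")
}
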