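#' @title Packaged antler registry
#' @description Loads the packaged domain model: the catalogue of named
#'   antler elements (tines, beams, processes) with their structural
#'   dependencies, the seven skull indices used as positional landmarks on
#'   the burr cross-section, the species sample table (number of adult
#'   antlers per species, left and right counted separately), the curated
#'   species-level element-frequency registry, and the fixed rooted species
#'   topology used for ancestral state reconstruction.
#'
#' @param dir Directory containing the fixture files
#'   (`elements.json`, `species.csv`, `frequencies.json`, `topology.nwk`).
#'   Defaults to the copies shipped with the package.
#' @param tree_file Optional replacement Newick file for the topology; the
#'   tree must be rooted, binary, and its leaf set must equal the species
#'   table (underscores in tip labels stand for spaces).
#'
#' @return An object of class `antler_registry`: a list with components
#'   `elements` (data.frame: code, name, category, pocock_code, requires),
#'   `skull_indices` (data.frame), `species` (data.frame: species, genus,
#'   n_antlers, clades), `frequencies` (data.frame: species, element,
#'   frequency), and `topology` (an [ape::read.tree()] `phylo`).
#' @export
#' @examples
#' reg <- load_registry()
#' nrow(reg$species)            # 25 species
#' length(unique(reg$species$genus))  # 16 genera
load_registry <- function(dir = system.file("extdata", package = "antlerphy"),
                          tree_file = file.path(dir, "topology.nwk")) {
  files <- c(elements = file.path(dir, "elements.json"),
             species = file.path(dir, "species.csv"),
             frequencies = file.path(dir, "frequencies.json"),
             topology = tree_file)
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop("missing registry fixture file(s): ", paste(missing, collapse = ", "))

  cat_json <- jsonlite::read_json(files[["elements"]])
  elements <- do.call(rbind, lapply(cat_json$elements, function(e) {
    data.frame(code = e$code, name = e$name, category = e$category,
               pocock_code = if (is.null(e$pocock_code)) NA_character_ else e$pocock_code,
               stringsAsFactors = FALSE)
  }))
  elements$requires <- lapply(cat_json$elements,
                              function(e) as.character(unlist(e$requires)))
  skull <- do.call(rbind, lapply(cat_json$skull_indices, function(s) {
    data.frame(code = s$code, description = s$description,
               stringsAsFactors = FALSE)
  }))

  species <- utils::read.csv(files[["species"]], stringsAsFactors = FALSE)

  freq_json <- jsonlite::read_json(files[["frequencies"]])
  frequencies <- data.frame(
    species = vapply(freq_json, function(x) x$species, ""),
    element = vapply(freq_json, function(x) x$element, ""),
    stringsAsFactors = FALSE)
  frequencies$frequency <- lapply(freq_json, function(x) x$frequency)

  topology <- ape::read.tree(files[["topology"]])

  reg <- structure(list(elements = elements, skull_indices = skull,
                        species = species, frequencies = frequencies,
                        topology = topology),
                   class = "antler_registry")
  validate_registry(reg)
  reg
}

#' Validate an antler registry
#'
#' Checks the structural invariants: unique element codes, recognised
#' categories, acyclic dependency graph referencing only known codes,
#' exactly the seven skull index codes, unique species, one frequency entry
#' per (species, element) pair, and a rooted binary topology whose leaves
#' match the species table.
#'
#' @param reg An `antler_registry`.
#' @return `reg`, invisibly; signals an error on any violation.
#' @export
validate_registry <- function(reg) {
  el <- reg$elements
  if (anyDuplicated(el$code))
    stop("duplicate element codes in registry")
  if (!all(el$category %in% c("tine", "beam", "process")))
    stop("element category must be one of tine, beam, process")
  known <- el$code
  for (i in seq_len(nrow(el))) {
    bad <- setdiff(el$requires[[i]], known)
    if (length(bad))
      stop("element ", el$code[i], " requires unknown code(s): ",
           paste(bad, collapse = ", "))
  }
  # acyclicity of the dependency graph by iterated leaf stripping
  deps <- stats::setNames(el$requires, el$code)
  remaining <- names(deps)
  repeat {
    free <- remaining[vapply(deps[remaining], function(d)
      !any(d %in% remaining), TRUE)]
    if (!length(free)) break
    remaining <- setdiff(remaining, free)
  }
  if (length(remaining))
    stop("element dependency graph has a cycle involving: ",
         paste(remaining, collapse = ", "))

  want <- c("SR", "TR", "IFST", "SPO", "LMOF", "PEOI", "BN")
  if (!setequal(reg$skull_indices$code, want) ||
      nrow(reg$skull_indices) != 7L)
    stop("skull index codes must be exactly: ", paste(want, collapse = ", "))

  sp <- reg$species
  if (anyDuplicated(sp$species)) stop("duplicate species in species table")
  if (any(sp$n_antlers < 0)) stop("n_antlers must be non-negative")

  fr <- reg$frequencies
  if (anyDuplicated(fr[c("species", "element")]))
    stop("duplicate (species, element) frequency entries")
  if (!all(fr$species %in% sp$species))
    stop("frequency entries for unknown species")
  if (!all(fr$element %in% known))
    stop("frequency entries for unknown elements")
  invisible(lapply(fr$frequency, resolve_frequency))

  tr <- reg$topology
  if (!inherits(tr, "phylo")) stop("topology must be a phylo tree")
  if (!ape::is.rooted(tr)) stop("topology must be rooted")
  if (!ape::is.binary(tr)) stop("topology must be binary")
  tips <- gsub("_", " ", tr$tip.label)
  if (!setequal(tips, sp$species))
    stop("topology leaves do not match the species table: ",
         paste(c(setdiff(tips, sp$species), setdiff(sp$species, tips)),
               collapse = ", "))
  invisible(reg)
}

#' @export
print.antler_registry <- function(x, ...) {
  cat("antler registry:\n")
  cat("  ", nrow(x$elements), "elements (",
      sum(x$elements$category == "tine"), "tines,",
      sum(x$elements$category == "beam"), "beams,",
      sum(x$elements$category == "process"), "processes )\n")
  cat("  ", nrow(x$species), "species,",
      length(unique(x$species$genus)), "genera,",
      sum(x$species$n_antlers), "adult antlers\n")
  cat("  ", nrow(x$frequencies), "frequency entries;",
      length(x$topology$tip.label), "topology leaves\n")
  invisible(x)
}

## fixed mapping from qualitative frequency classes to percentages
.freq_tokens <- c(all = 100, almost_all = 95, common = 50, rare = 10,
                  very_rare = 2, absent = 0)

#' Resolve a frequency class to a percentage
#'
#' Frequency entries in the registry are either numeric percentages in
#' \[0, 100\] or qualitative tokens. Tokens map by the fixed table
#' `all -> 100`, `almost_all -> 95`, `common -> 50`, `rare -> 10`,
#' `very_rare -> 2`, `absent -> 0`, chosen so that coding the resolved
#' percentages reproduces the qualitative state assignments used in the
#' species descriptions.
#'
#' @param entry A single numeric percentage or one of the tokens above.
#' @return A numeric percentage in \[0, 100\].
#' @export
#' @examples
#' resolve_frequency(100)      # 100
#' resolve_frequency("rare")   # 10
#' resolve_frequency("absent") # 0
resolve_frequency <- function(entry) {
  if (is.list(entry) && length(entry) == 1L) entry <- entry[[1L]]
  if (is.numeric(entry)) {
    if (length(entry) != 1L || is.na(entry) || entry < 0 || entry > 100)
      stop("numeric frequency must be a single value in [0, 100]")
    return(as.numeric(entry))
  }
  if (is.character(entry) && length(entry) == 1L &&
      entry %in% names(.freq_tokens))
    return(unname(.freq_tokens[[entry]]))
  stop("unknown frequency class: ", deparse(entry))
}

#' Species-by-element percentage matrix from the frequency registry
#'
#' Resolves every registry frequency entry to a percentage; pairs with no
#' entry default to 0 (absent).
#'
#' @param reg An `antler_registry`.
#' @param elements Element codes to include (default: all catalogued
#'   elements that have at least one non-zero entry).
#' @return A numeric matrix, rows named by species, columns by element code.
#' @export
registry_percentages <- function(reg, elements = NULL) {
  fr <- reg$frequencies
  fr$pct <- vapply(fr$frequency, resolve_frequency, 0)
  if (is.null(elements)) {
    elements <- intersect(reg$elements$code, unique(fr$element[fr$pct > 0]))
  }
  m <- matrix(0, nrow = nrow(reg$species), ncol = length(elements),
              dimnames = list(reg$species$species, elements))
  keep <- fr$element %in% elements
  m[cbind(fr$species[keep], fr$element[keep])] <- fr$pct[keep]
  m
}

#' Look up one frequency entry
#'
#' @param reg An `antler_registry`.
#' @param species Binomial species name.
#' @param element Element code.
#' @return The stored frequency class (number or token); `"absent"` when the
#'   pair is unlisted.
#' @export
registry_frequency <- function(reg, species, element) {
  hit <- reg$frequencies$species == species & reg$frequencies$element == element
  if (!any(hit)) return("absent")
  reg$frequencies$frequency[[which(hit)[1L]]]
}

#' Transitive closure of an element's structural requirements
#'
#' @param reg An `antler_registry`.
#' @param code Element code.
#' @return Character vector of all element codes transitively required.
#' @export
element_requirements <- function(reg, code) {
  deps <- stats::setNames(reg$elements$requires, reg$elements$code)
  if (!code %in% names(deps)) stop("unknown element code: ", code)
  out <- character(0)
  frontier <- deps[[code]]
  while (length(frontier)) {
    out <- union(out, frontier)
    frontier <- setdiff(unique(unlist(deps[frontier])), out)
  }
  out
}
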