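#' Code a percentage into a character state
#'
#' The three-state coding of within-species element frequency: state 2 when
#' the element is observed in 80\% or more of the species' adult antlers,
#' state 1 when observed in less than 80\% but at least once, and state 0
#' when observed in no specimen. The 80\% boundary is inclusive for state 2,
#' and any single observation (any percentage above exactly 0) forces state
#' 1 or above.
#'
#' @param pct Numeric vector of percentages in \[0, 100\].
#' @return Integer vector of states in \{0, 1, 2\}.
#' @export
#' @examples
#' code_state(c(0, 0.5, 40, 79.9, 80, 100))  # 0 1 1 1 2 2
code_state <- function(pct) {
  if (!is.numeric(pct) || anyNA(pct) || any(pct < 0 | pct > 100))
    stop("percentages must be numeric in [0, 100]")
  ifelse(pct >= 80, 2L, ifelse(pct > 0, 1L, 0L))
}

#' Validate a specimen matrix
#'
#' A specimen matrix has one row per antler with the metadata columns
#' `specimen_id`, `species`, `side` ("left"/"right") and `age`
#' ("adult"/"juvenile"/"unknown"), followed by one binary (0/1) column per
#' element code. No (specimen_id, side) pair may repeat and no cell may be
#' missing.
#'
#' @param specimens A data.frame.
#' @param registry Optional `antler_registry`; when given, species and
#'   element codes are checked against it.
#' @return `specimens`, invisibly; errors on violations.
#' @export
validate_specimens <- function(specimens, registry = NULL) {
  meta <- c("specimen_id", "species", "side", "age")
  if (!all(meta %in% names(specimens)))
    stop("specimen matrix must have columns: ", paste(meta, collapse = ", "))
  el_cols <- setdiff(names(specimens), meta)
  if (!length(el_cols)) stop("specimen matrix has no element columns")
  vals <- as.matrix(specimens[el_cols])
  if (anyNA(vals)) stop("missing observations are disallowed, not imputed")
  if (!all(vals %in% c(0, 1))) stop("element columns must be binary 0/1")
  if (!all(specimens$side %in% c("left", "right")))
    stop("side must be 'left' or 'right'")
  if (anyDuplicated(specimens[c("specimen_id", "side")]))
    stop("duplicate (specimen_id, side) rows")
  if (!is.null(registry)) {
    bad_sp <- setdiff(unique(specimens$species), registry$species$species)
    if (length(bad_sp))
      stop("unknown species in specimen matrix: ",
           paste(bad_sp, collapse = ", "))
    bad_el <- setdiff(el_cols, registry$elements$code)
    if (length(bad_el))
      stop("unknown element columns: ", paste(bad_el, collapse = ", "))
  }
  invisible(specimens)
}

#' Species-level element percentages from a specimen matrix
#'
#' Only adult rows enter the percentages (juvenile and unknown-age antlers
#' are kept in the matrix for diagram work but excluded from coding); left
#' and right antlers count separately, each antler once. Species with zero
#' adult antlers are reported and excluded.
#'
#' @param specimens A specimen matrix (see [validate_specimens()]).
#' @param registry Optional registry for validation.
#' @return A numeric matrix of percentages (species x element), with
#'   attributes `n_adult` (named vector of adult antler counts) and
#'   `excluded` (species with no adult antlers).
#' @export
species_percentages <- function(specimens, registry = NULL) {
  validate_specimens(specimens, registry)
  meta <- c("specimen_id", "species", "side", "age")
  el_cols <- setdiff(names(specimens), meta)
  adults <- specimens[specimens$age == "adult", , drop = FALSE]
  all_species <- unique(specimens$species)
  n_adult <- vapply(all_species,
                    function(s) sum(adults$species == s), 0L)
  excluded <- all_species[n_adult == 0L]
  if (length(excluded))
    warning("species with zero adult antlers excluded from coding: ",
            paste(excluded, collapse = ", "))
  keep <- setdiff(all_species, excluded)
  pct <- matrix(NA_real_, length(keep), length(el_cols),
                dimnames = list(keep, el_cols))
  for (s in keep) {
    rows <- adults[adults$species == s, el_cols, drop = FALSE]
    pct[s, ] <- 100 * colSums(rows) / nrow(rows)
  }
  attr(pct, "n_adult") <- n_adult[keep]
  attr(pct, "excluded") <- excluded
  pct
}

#' Code a percentage table into a character state matrix
#'
#' @param pct A species-by-element percentage matrix, e.g. from
#'   [species_percentages()] or [registry_percentages()].
#' @param n Optional named vector of adult antler counts per species
#'   (provenance; taken from `attr(pct, "n_adult")` when present).
#' @return An object of class `character_state_matrix`: an integer matrix
#'   of states in \{0, 1, 2\} with attributes `pct` (the percentages) and
#'   `n` (the sample sizes).
#' @export
code_character_matrix <- function(pct, n = attr(pct, "n_adult")) {
  states <- apply(pct, c(1, 2), code_state)
  structure(states, pct = unclass(pct)[, , drop = FALSE], n = n,
            class = c("character_state_matrix", class(states)))
}

#' @export
print.character_state_matrix <- function(x, ...) {
  cat("character state matrix:", nrow(x), "species x", ncol(x),
      "elements\n")
  m <- x
  attributes(m) <- attributes(x)[c("dim", "dimnames")]
  print(m)
  invisible(x)
}

#' Character state matrix from the packaged frequency registry
#'
#' Resolves the curated species-level frequencies to percentages and codes
#' them; sample sizes come from the species table.
#'
#' @param registry An `antler_registry`.
#' @param elements Optional element codes (default: all with an entry).
#' @return A `character_state_matrix`.
#' @export
states_from_registry <- function(registry, elements = NULL) {
  pct <- registry_percentages(registry, elements)
  n <- stats::setNames(registry$species$n_antlers, registry$species$species)
  code_character_matrix(pct, n = n[rownames(pct)])
}

#' Write a character state matrix as CSV
#'
#' @param states A `character_state_matrix` (or plain matrix).
#' @param file Output path.
#' @export
write_states_csv <- function(states, file) {
  df <- data.frame(species = rownames(states), unclass(states)[, , drop = FALSE],
                   check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a character state matrix from CSV
#'
#' @param file CSV written by [write_states_csv()] (first column `species`,
#'   remaining columns element states).
#' @return A `character_state_matrix` (without provenance attributes).
#' @export
read_states_csv <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$species
  storage.mode(m) <- "integer"
  if (!all(m %in% 0:2)) stop("states must be 0, 1 or 2")
  structure(m, class = c("character_state_matrix", class(m)))
}

#' Export states as a NEXUS character block
#'
#' Writes a minimal NEXUS file (DATA block, symbols 0 1 2) for
#' interoperability with standard phylogenetics software.
#'
#' @param states A species-by-element state matrix.
#' @param file Output path.
#' @export
write_states_nexus <- function(states, file) {
  taxa <- gsub(" ", "_", rownames(states))
  lines <- c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(states), ncol(states)),
    "  FORMAT DATATYPE=STANDARD SYMBOLS=\"012\" MISSING=? GAP=-;",
    "  MATRIX")
  width <- max(nchar(taxa)) + 2L
  for (i in seq_len(nrow(states)))
    lines <- c(lines, sprintf("    %-*s%s", width, taxa[i],
                              paste(states[i, ], collapse = "")))
  lines <- c(lines, "  ;", "END;",
             sprintf("[Characters: %s]",
                     paste(colnames(states), collapse = " ")))
  writeLines(lines, file)
  invisible(file)
}

#' Write / read a specimen matrix as CSV
#'
#' @param specimens A specimen matrix data.frame.
#' @param file Path.
#' @export
write_specimens_csv <- function(specimens, file) {
  utils::write.csv(specimens, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_specimens_csv
#' @export
read_specimens_csv <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  validate_specimens(df)
  df
}
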