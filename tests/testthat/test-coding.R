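make_specimens <- function(per_species, elements, prob = NULL,
                           age = "adult") {
  rows <- list()
  for (s in names(per_species)) {
    k <- per_species[[s]]
    if (k == 0) next
    m <- matrix(0L, k, length(elements), dimnames = list(NULL, elements))
    rows[[s]] <- data.frame(
      specimen_id = sprintf("%s%03d", gsub(" ", "", s),
                            ceiling(seq_len(k) / 2)),
      species = s, side = rep_len(c("left", "right"), k), age = age, m,
      check.names = FALSE, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

test_that("coding thresholds: 2 at >= 80, 1 in (0, 80), 0 only at 0", {
  expect_identical(code_state(80), 2L)
  expect_identical(code_state(40), 1L)
  expect_identical(code_state(0), 0L)
  expect_identical(code_state(100), 2L)
  expect_identical(code_state(79.999), 1L)
  expect_identical(code_state(0.001), 1L)   # one observation forces state 1
  expect_error(code_state(101), "\\[0, 100\\]")
  expect_error(code_state(-2), "\\[0, 100\\]")
  # monotone, piecewise constant with breakpoints only at 0+ and 80
  grid <- seq(0, 100, by = 0.5)
  st <- code_state(grid)
  expect_true(all(diff(st) >= 0))
  expect_setequal(grid[which(diff(st) != 0) + 1L], c(0.5, 80))
})

test_that("species percentages use adult antlers only, each counted once", {
  sp <- make_specimens(c("Cervus nippon" = 12, "Dama dama" = 18), "B")
  sp$B[sp$species == "Cervus nippon"] <- 1L
  sp$B[sp$species == "Dama dama"][1:2] <- 1L
  # juveniles carrying the element must not alter the percentages
  juv <- make_specimens(c("Dama dama" = 4), "B", age = "juvenile")
  juv$B <- 1L
  juv$specimen_id <- paste0("juv", seq_len(nrow(juv)))
  pct <- species_percentages(rbind(sp, juv))
  expect_equal(unname(pct["Cervus nippon", "B"]), 100)
  expect_equal(unname(pct["Dama dama", "B"]), 200 / 18)
  expect_equal(round(pct["Dama dama", "B"], 1), 11.1)
  expect_equal(attr(pct, "n_adult")[["Dama dama"]], 18L)
  # zero observations give exactly 0
  sp0 <- make_specimens(c("Alces alces" = 7), "B")
  expect_equal(unname(species_percentages(sp0)["Alces alces", "B"]), 0)
})

test_that("species without adults are reported and excluded", {
  sp <- make_specimens(c("Cervus nippon" = 4), "B")
  juv <- make_specimens(c("Axis axis" = 2), "B", age = "juvenile")
  expect_warning(pct <- species_percentages(rbind(sp, juv)),
                 "Axis axis")
  expect_false("Axis axis" %in% rownames(pct))
  expect_equal(attr(pct, "excluded"), "Axis axis")
})

test_that("malformed specimen matrices are rejected", {
  sp <- make_specimens(c("Cervus nippon" = 4), "B")
  dup <- rbind(sp, sp[1, ])
  expect_error(validate_specimens(dup), "duplicate")
  na <- sp; na$B[2] <- NA
  expect_error(validate_specimens(na), "disallowed")
  bad <- sp; bad$B[2] <- 3
  expect_error(validate_specimens(bad), "binary")
  reg <- load_registry()
  alien <- sp; alien$species <- "Megaloceros giganteus"
  expect_error(validate_specimens(alien, reg), "unknown species")
})

test_that("state matrices round-trip through CSV and export to NEXUS", {
  reg <- load_registry()
  states <- states_from_registry(reg)
  expect_true(all(states %in% 0:2))
  expect_equal(unname(states["Panolia eldii", "M"]), 2L)
  expect_equal(unname(states["Elaphurus davidianus", "M"]), 1L)
  expect_equal(unname(states["Hydropotes inermis", "L"]), 0L)
  f <- tempfile(fileext = ".csv")
  write_states_csv(states, f)
  back <- read_states_csv(f)
  expect_equal(unclass(back)[, , drop = FALSE][rownames(states), ],
               matrix(as.integer(states), nrow(states),
                      dimnames = dimnames(states)))
  nex <- tempfile(fileext = ".nex")
  write_states_nexus(states, nex)
  txt <- readLines(nex)
  expect_true(any(grepl("^#NEXUS", txt)))
  expect_true(any(grepl(sprintf("NTAX=%d NCHAR=%d", nrow(states),
                                ncol(states)), txt)))
})

test_that("coding recovers simulated generating frequencies", {
  st <- matrix(c(2L, 1L, 0L), 1, 3,
               dimnames = list("Cervus nippon", c("E1", "E2", "E3")))
  sp <- simulate_specimens(st, sim_config(seed = 42,
                                          specimens_per_species = 400))
  pct <- species_percentages(sp)
  # binomial 3-standard-error bands around 95%, 30% and exactly 0
  expect_lt(abs(pct[1, "E1"] - 95), 3 * sqrt(0.95 * 0.05 / 400) * 100)
  expect_lt(abs(pct[1, "E2"] - 30), 3 * sqrt(0.3 * 0.7 / 400) * 100)
  expect_identical(unname(pct[1, "E3"]), 0)
})
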