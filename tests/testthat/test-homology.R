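test_that("length ratio separates tines/beams from processes, strictly", {
  expect_equal(classify_category(50, 20), "tine_or_beam")
  expect_equal(classify_category(30, 20), "process")
  expect_equal(classify_category(40, 20), "process")  # exactly twice
  expect_error(classify_category(-1, 5), "positive")
})

test_that("signatures capture depth, partner and positional order", {
  d <- build_diagram(fig5_tree())
  sg <- extract_signature(d, "B")
  expect_equal(sg$depth, 1L)
  expect_equal(sg$partner, "L")
  expect_equal(extract_signature(d, "CI")$depth, 3L)
  expect_equal(extract_signature(d, "CI")$partner, "CO")
  # brow tine sits lateral of the arterial impression, medial of SR
  rel <- sg$relations
  expect_equal(rel$predicate[rel$object == "IFST"], "lateral_to")
  expect_equal(rel$predicate[rel$object == "SR"], "medial_to")
  expect_error(extract_signature(d, "QQ"), "absent")
})

test_that("marks at identical angles coincide in the signature", {
  d <- build_diagram(fig5_tree())
  # CO's direction (120) coincides with LMOF (120) under any tolerance
  sg <- extract_signature(d, "CO", tolerance = 0.5)
  grp <- Filter(function(g) "self" %in% g, sg$order)
  expect_true("LMOF" %in% grp[[1L]])
})

test_that("homology matching is reflexive and symmetric", {
  d <- build_diagram(fig5_tree())
  sigs <- lapply(c("B", "L", "T", "H"), extract_signature, diagram = d)
  for (s in sigs) expect_true(match_elements(s, s)$homologous)
  ab <- match_elements(sigs[[1L]], sigs[[2L]])
  ba <- match_elements(sigs[[2L]], sigs[[1L]])
  expect_equal(ab$homologous, ba$homologous)
})

test_that("homology verdicts survive whole-diagram rotation and scaling", {
  d0 <- build_diagram(fig5_tree(), fig5_skull_marks())
  d1 <- build_diagram(fig5_tree(shift = 73), fig5_skull_marks(shift = 73))
  for (el in c("B", "L", "T", "H", "CI", "CO")) {
    m <- match_elements(extract_signature(d0, el), extract_signature(d1, el))
    expect_true(m$homologous)
  }
  # uniform scaling: same geometry on a doubled circumference
  double_tree <- local({
    s <- function(p) 2 * p
    H <- tine_node("H", "beam", 240, 50,
                   fork = list(ridge = s(140), boundary = s(220),
                               child_ridge = c(s(0), s(300))),
                   children = list(tine_node("CI"), tine_node("CO")))
    L <- tine_node("L", "beam", 300, 60,
                   fork = list(ridge = s(100), boundary = s(250),
                               child_ridge = c(s(55), s(240))),
                   children = list(H, tine_node("T")))
    root <- tine_node("base", "base", 120, 80,
                      fork = list(ridge = s(10), boundary = s(330),
                                  child_ridge = c(s(110), s(174))),
                      children = list(L, tine_node("B")))
    tine_tree(root, circumference = 720)
  })
  d2 <- build_diagram(double_tree)
  expect_equal(d2$branching_directions, d0$branching_directions)
})

test_that("same-position second-fork tines match; shifted ones do not", {
  da <- build_diagram(second_fork_tree(TRUE))
  db <- build_diagram(second_fork_tree(TRUE))
  dc <- build_diagram(second_fork_tree(FALSE))
  same <- match_elements(extract_signature(da, "a2"),
                         extract_signature(db, "a2"))
  expect_true(same$homologous)
  diff <- match_elements(extract_signature(da, "a2"),
                         extract_signature(dc, "a2"))
  expect_false(diff$homologous)
  expect_true(any(grepl("BN", diff$violations)))
})

test_that("mirrored antlers are homologous to their originals", {
  for (seed in c(2, 5, 9)) {
    a <- synthetic_antler(sim_config(seed = seed), max_depth = 3)
    da <- build_diagram(a)
    dm <- build_diagram(mirror_antler(a))
    for (el in names(da$branching_directions)) {
      m <- match_elements(extract_signature(da, el),
                          extract_signature(dm, el))
      expect_true(m$homologous)
    }
  }
})

test_that("species consensus follows the majority, weighted by sample size", {
  sA <- extract_signature(build_diagram(second_fork_tree(TRUE)), "a2")
  sC <- extract_signature(build_diagram(second_fork_tree(FALSE)), "a2")
  # unanimous specimens reproduce their shared signature exactly
  cons0 <- canonical_signature(list(sA, sA, sA))
  expect_true(match_elements(cons0, sA)$homologous)
  # a 2:1 majority wins ...
  cons <- canonical_signature(list(sA, sA, sC))
  expect_true(match_elements(cons, sA)$homologous)
  expect_false(match_elements(cons, sC)$homologous)
  # ... and ties break toward the largest sample
  tied <- canonical_signature(list(sA, sC), weights = c(10, 2))
  expect_true(match_elements(tied, sA)$homologous)
})
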