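mrca_of <- function(tr, tips) {
  ids <- match(tips, tr$tip.label)
  ape::getMRCA(tr, ids)
}

test_that("Dollo placement on worked examples", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  nm <- node_names(tr)
  # all present: gain at the root stem, zero losses
  all1 <- dollo_presence(tr, c(A = 1, B = 1, C = 1, D = 1))
  expect_equal(all1$gain_edge, clade_node(tr, nm[5]))
  expect_equal(all1$n_losses, 0L)
  # a single present tip: gain on its terminal edge
  one <- dollo_presence(tr, c(A = 0, B = 0, C = 1, D = 0))
  expect_equal(one$gain_edge, which(tr$tip.label == "C"))
  expect_equal(one$n_losses, 0L)
  # A and C present: gain at the root stem, losses on B and D
  ac <- dollo_presence(tr, c(A = 1, B = 0, C = 1, D = 0))
  expect_equal(ac$gain_edge, length(tr$tip.label) + 1L)
  expect_setequal(ac$loss_edges, which(tr$tip.label %in% c("B", "D")))
  # no presence at all
  none <- dollo_presence(tr, c(A = 0, B = 0, C = 0, D = 0))
  expect_true(is.na(none$gain_edge))
  expect_false(any(none$presence))
  expect_error(dollo_presence(tr, c(A = 1, B = 0, C = 1)), "unlabelled")
})

test_that("ACCTRAN refinement on worked examples", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  pres <- rep(TRUE, 7)
  # one discordant tip: single change on its terminal edge
  r <- acctran_refine(tr, pres, c(A = 2, B = 1, C = 2, D = 2),
                      subtree_root = 5L)
  expect_equal(r$n_changes, 1L)
  expect_equal(r$change_edges, which(tr$tip.label == "B"))
  expect_equal(r$root_grade, 2)
  # all tips grade 2: no changes anywhere
  r2 <- acctran_refine(tr, pres, c(A = 2, B = 2, C = 2, D = 2),
                       subtree_root = 5L)
  expect_equal(r2$n_changes, 0L)
  expect_true(all(r2$grades == 2))

  tr2 <- ape::read.tree(text = "(A,(B,(C,D)));")
  pres2 <- rep(TRUE, 7)
  # ambiguous root resolves to 2; the downgrade goes on the inner clade's
  # stem and the regain on C's terminal edge
  r3 <- acctran_refine(tr2, pres2, c(A = 2, B = 1, C = 2, D = 1),
                       subtree_root = 5L)
  expect_equal(r3$root_grade, 2)
  expect_equal(r3$n_changes, 2L)
  inner <- mrca_of(tr2, c("B", "C", "D"))
  expect_setequal(r3$change_edges, c(inner, which(tr2$tip.label == "C")))
})

test_that("two-layer reconstruction combines Dollo and ACCTRAN", {
  tr <- ape::read.tree(text = "(((A,B),C),(D,E));")
  rec <- reconstruct_character(tr, c(A = 2, B = 2, C = 0, D = 1, E = 0), "x")
  root <- length(tr$tip.label) + 1L
  expect_equal(rec$gain_edge_id, root)
  expect_setequal(rec$loss_edge_ids, which(tr$tip.label %in% c("C", "E")))
  expect_equal(unname(rec$node_states[node_names(tr)[root]]), 2)
  # with E pruned (state 0), D's lineage is the path root -> (D,E) -> D;
  # ACCTRAN puts the 2 -> 1 change on its uppermost edge
  expect_equal(rec$grade_change_edge_ids, mrca_of(tr, c("D", "E")))
  expect_equal(unname(rec$node_states["D"]), 1)
  # degenerate inputs
  rec0 <- reconstruct_character(tr, c(A = 0, B = 0, C = 0, D = 0, E = 0))
  expect_true(all(rec0$node_states == 0))
  expect_true(is.na(rec0$gain_edge))
  rec2 <- reconstruct_character(tr, c(A = 2, B = 2, C = 2, D = 2, E = 2))
  expect_true(all(rec2$node_states == 2))
  expect_equal(rec2$gain_edge_id, root)
  expect_length(rec2$loss_edge_ids, 0L)
  expect_length(rec2$grade_change_edge_ids, 0L)
  # a character seen once, at low frequency: gained on that terminal edge
  rec1 <- reconstruct_character(tr, c(A = 0, B = 0, C = 1, D = 0, E = 0))
  expect_equal(rec1$gain_edge_id, which(tr$tip.label == "C"))
  expect_equal(unname(rec1$node_states["C"]), 1)
})

test_that("reconstruction is idempotent on its own tip states", {
  tr <- ape::read.tree(text = "(((A,B),(C,D)),(E,(F,G)));")
  set.seed(99)
  for (i in 1:20) {
    tips <- setNames(sample(0:2, 7, replace = TRUE), tr$tip.label)
    r1 <- reconstruct_character(tr, tips)
    r2 <- reconstruct_character(tr, tip_states_of(r1))
    expect_identical(r1$node_states, r2$node_states)
    expect_identical(r1$gain_edge, r2$gain_edge)
    expect_identical(r1$loss_edges, r2$loss_edges)
    expect_identical(r1$grade_change_edges, r2$grade_change_edges)
  }
})

test_that("grade change counts agree with an independent Fitch oracle", {
  skip_if_not_installed("phangorn")
  set.seed(7)
  for (i in 1:15) {
    tr <- ape::rtree(8, br = NULL)
    grades <- setNames(sample(1:2, 8, replace = TRUE), tr$tip.label)
    mine <- acctran_refine(tr, rep(TRUE, 15), grades,
                           subtree_root = 9L)$n_changes
    dat <- phangorn::phyDat(matrix(as.character(grades), ncol = 1,
                                   dimnames = list(names(grades), NULL)),
                            type = "USER", levels = c("1", "2"))
    expect_equal(mine, phangorn::fitch(tr, dat))
  }
})

test_that("ancestral antlers respect structural dependencies and points", {
  reg <- load_registry()
  tr <- reg$topology
  states <- states_from_registry(reg)
  recons <- reconstruct_all(tr, states)
  root <- assemble_ancestral_antler("Cervidae", recons, reg)
  expect_setequal(root$elements, c("B", "L"))
  expect_equal(root$points, 2L)
  expect_equal(nrow(root$violations), 0L)
  cervini <- assemble_ancestral_antler("Cervini", recons, reg)
  expect_setequal(cervini$elements, c("B", "L", "T", "H", "BWP"))
  expect_equal(cervini$points, 3L)  # the brow process adds no point
  # an element whose requirement is absent is reported, not repaired
  st2 <- states
  st2[, "L"] <- 0L
  rec2 <- reconstruct_all(tr, st2)
  broken <- assemble_ancestral_antler("Cervini", rec2, reg)
  expect_true("T" %in% broken$violations$element)
  expect_false("T" %in% broken$elements)
  # empty antler
  hyd <- reconstruct_all(tr, states[, c("B", "L"), drop = FALSE])
  empty <- assemble_ancestral_antler("Hydropotes_inermis", hyd, reg)
  expect_length(empty$elements, 0L)
  expect_equal(empty$points, 0L)
})
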