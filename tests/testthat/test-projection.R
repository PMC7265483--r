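test_that("opposite_point halves the circumference and is an involution", {
  expect_equal(opposite_point(0, 12), 6)
  expect_equal(opposite_point(9, 12), 3)
  expect_equal(opposite_point(0, 2), 1)
  expect_error(opposite_point(1, 0), "positive")
  set.seed(11)
  for (i in 1:200) {
    C <- runif(1, 1, 500)
    p <- runif(1, 0, C)
    expect_equal(opposite_point(opposite_point(p, C), C), p,
                 tolerance = 1e-9)
  }
})

test_that("remap endpoints: ridge maps to opposite, boundary is fixed", {
  # worked case: C = 24, ridge 0, boundary 18; shadow arc from 12 to 18
  expect_equal(remap_across_tine(0, 0, 18, C = 24), 12)
  expect_equal(remap_across_tine(18, 0, 18, C = 24), 18)
  # midpoint maps to the shadow-arc midpoint: X = 3 from the opposite point
  expect_equal(remap_across_tine(9, 0, 18, C = 24), 15)
  # degenerate prorating interval: ridge on the boundary
  expect_equal(remap_across_tine(5, 7, 7, C = 24), 7)
  expect_error(remap_across_tine(1, 0, 18, C = 24, opposite = 5),
               "opposite")
})

test_that("remap is strictly monotone and lands on the shadow arc", {
  set.seed(23)
  for (i in 1:300) {
    C <- runif(1, 10, 400)
    r <- runif(1, 0, C)
    b <- (r + runif(1, 0.05 * C, 0.95 * C)) %% C
    o <- opposite_point(r, C)
    span <- ((b - r) %% C + C) %% C
    xs <- sort(runif(25, 1e-6, span - 1e-6))
    alpha <- (r + xs) %% C
    ys <- vapply(alpha, remap_across_tine, 0, ridge = r, boundary = b, C = C)
    # distances from the opposite point along the shadow arc increase with x
    S <- min(((b - o) %% C + C) %% C, ((o - b) %% C + C) %% C)
    dist_o <- vapply(ys, function(y)
      min(((y - o) %% C + C) %% C, ((o - y) %% C + C) %% C), 0)
    expect_true(all(diff(dist_o) > 0))
    expect_true(all(dist_o <= S + 1e-9))
  }
})

test_that("unmap inverts remap on both sides of the overlapping tine", {
  set.seed(31)
  for (i in 1:200) {
    C <- runif(1, 10, 400)
    r <- runif(1, 0, C)
    b <- (r + runif(1, 0.05 * C, 0.95 * C)) %% C
    span <- ((b - r) %% C + C) %% C
    side <- sample(c(1, -1), 1)
    x <- runif(1, 1e-6, (if (side > 0) span else C - span) - 1e-6)
    alpha <- ((r + side * x) %% C + C) %% C
    y <- remap_across_tine(alpha, r, b, C = C)
    expect_equal(unmap_across_tine(y, r, b, C = C, side = side), alpha,
                 tolerance = 1e-6)
  }
})

test_that("projection composes remaps down the path to the burr", {
  tr <- fig5_tree()
  # element at the first fork with no intervening tine: direct conversion
  expect_equal(project_to_burr(tr, "B"), opposite_point(174, 360))
  expect_equal(project_to_burr(tr, "L"), opposite_point(110, 360))
  # deeper elements whose grooves stay on their own side pass unchanged
  expect_equal(project_to_burr(tr, "CI"), 180)
  expect_equal(project_to_burr(tr, "CO"), 120)
  expect_error(project_to_burr(tr, "ZZ"), "absent")
})

test_that("a position covered by a proximal tine is prorated across it", {
  # distal element anchored so its direction lands on the proximal tine P:
  # the projected angle must be the remapped position, computed by hand
  x1 <- tine_node("X1", "tine", 80, 15)
  x2 <- tine_node("X2", "tine", 70, 15)
  D <- tine_node("D", "beam", 120, 25,
                 fork = list(ridge = 150, boundary = 250,
                             child_ridge = c(170, 240)),
                 children = list(x1, x2))
  P <- tine_node("P", "tine", 90, 18)
  root <- tine_node("base", "base", 50, 40,
                    fork = list(ridge = 100, boundary = 330,
                                child_ridge = c(40, 174)),
                    children = list(D, P))
  tr <- tine_tree(root)
  # X1's direction is opposite_point(170) = 350, inside P's arc (330..100):
  # remap with ridge 100, boundary 330, opposite 280: the point sits
  # x = (100 - 350) mod 360 = 110 into the minus-side arc of length 130,
  # shadow arc 280 -> 330 has length 50, so it lands at 280 + 110*50/130
  expect_equal(project_to_burr(tr, "X1"), 280 + 110 * 50 / 130,
               tolerance = 1e-9)
  # X2's direction 60 is also covered; same proration with x = 40
  expect_equal(project_to_burr(tr, "X2"), 280 + 40 * 50 / 130,
               tolerance = 1e-9)
  # D's own direction 220 is on its own side and passes unchanged
  expect_equal(project_to_burr(tr, "D"), 220)
})

test_that("projected positions are invariant to deleting the overlapping tine", {
  for (seed in 1:40) {
    tr <- overlap_tree(seed)
    before <- vapply(c("X1", "X2"), project_to_burr, 0, tree = tr)
    fork_before <- project_fork(tr, "X1/X2")
    tr2 <- delete_proximal_tine(tr, "P")
    after <- vapply(c("X1", "X2"), project_to_burr, 0, tree = tr2)
    fork_after <- project_fork(tr2, "X1/X2")
    expect_equal(after, before, tolerance = 1e-9)
    expect_equal(fork_after, fork_before, tolerance = 1e-9)
  }
})
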