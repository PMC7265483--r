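# Geometry fixtures shared across projection/homology tests.

# A sika-deer-like left antler: base forks into lower beam (L) and brow
# tine (B); L forks into higher beam (H) and trez tine (T); H forks into
# crown-inner (CI) and crown-outer (CO). Arc positions chosen so that no
# descent crosses a sibling tine (projection is mark-faithful).
fig5_tree <- function(shift = 0) {
  s <- function(p) ((p + shift) %% 360 + 360) %% 360
  H <- tine_node("H", "beam", 120, 25,
                 fork = list(ridge = s(140), boundary = s(220),
                             child_ridge = c(s(0), s(300))),
                 children = list(tine_node("CI"), tine_node("CO")))
  L <- tine_node("L", "beam", 150, 30,
                 fork = list(ridge = s(100), boundary = s(250),
                             child_ridge = c(s(55), s(240))),
                 children = list(H, tine_node("T")))
  root <- tine_node("base", "base", 60, 40,
                    fork = list(ridge = s(10), boundary = s(330),
                                child_ridge = c(s(110), s(174))),
                    children = list(L, tine_node("B")))
  tine_tree(root)
}

fig5_skull_marks <- function(shift = 0) {
  ((default_skull_marks() + shift) %% 360 + 360) %% 360
}

# Two-fork antler whose distal structure overlaps the proximal tine P: the
# positions stored above the root fork land on P's side of the burr, so
# projecting them exercises the proration. Geometry randomised per seed.
overlap_tree <- function(seed) {
  set.seed(seed)
  r0 <- runif(1, 0, 360)
  b0 <- (r0 + runif(1, 60, 300)) %% 360
  # child 1 of the root fork owns the + arc (r0, b0); child 2 is the
  # proximal tine P owning the complement
  rand_pos <- function(n = 1) runif(n, 0, 360)
  x1 <- tine_node("X1", "tine", 80, 15)
  x2 <- tine_node("X2", "tine", 70, 15)
  D <- tine_node("D", "beam", 120, 25,
                 fork = list(ridge = rand_pos(), boundary = rand_pos(),
                             child_ridge = rand_pos(2)),
                 children = list(x1, x2))
  P <- tine_node("P", "tine", 90, 18)
  root <- tine_node("base", "base", 50, 40,
                    fork = list(ridge = r0, boundary = b0,
                                child_ridge = c(rand_pos(), rand_pos())),
                    children = list(D, P))
  tine_tree(root)
}

# a brow-tine/lower-beam + second-fork fixture for the homology contrast:
# `a2_anterior` controls whether a2's branching direction falls anterior
# (TRUE) or posterior (FALSE) to the nerve-field boundary BN at 180 deg;
# everything else is identical, so only the positional order differs
second_fork_tree <- function(a2_anterior) {
  a2_dir <- if (a2_anterior) 160 else 240
  p2 <- tine_node("p2", "beam", 120, 25)
  L <- tine_node("p1", "beam", 150, 30,
                 fork = list(ridge = 140, boundary = 250,
                             child_ridge = c((a2_dir - 180) %% 360, 100)),
                 children = list(tine_node("a2"), p2))
  root <- tine_node("base", "base", 60, 40,
                    fork = list(ridge = 100, boundary = 330,
                                child_ridge = c(300, 174)),
                    children = list(L, tine_node("a1")))
  tine_tree(root)
}
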