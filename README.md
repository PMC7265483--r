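# antlerphy

Antler branching structure, burr diagrams, and ancestral state
reconstruction for deer (Cervidae).

Antlers fossilise well and vary spectacularly, but using them for
phylogeny requires knowing which tine of one species is homologous to
which tine of another — and for most of the family there has been no
anatomical procedure to decide that. `antlerphy` implements one: the
antler's surface grooves are treated as a flow field connecting every
point of the antler to the burr (the bony ring at its base), so the
branching direction of each tine and the position of each fork can be
projected onto the burr cross-section. The resulting circular **burr
diagram** summarises the whole branching structure of an antler, aligned
to skull landmarks, invariant to side and rotation. Diagrams are
compared symbolically (positional order, fork hierarchy, fork partners)
to decide homology; homologous elements become three-state characters
(2: in ≥ 80% of a species' adult antlers; 1: present but in < 80%;
0: absent), and characters are optimised on a fixed molecular phylogeny
by a two-layer parsimony — **Dollo** for presence (each element gained
exactly once, lost freely) and **Fitch/ACCTRAN** for the frequency grade
on the present subtree — to reconstruct the antlers of ancestral deer.

The package ships the curated domain fixtures (element catalogue with
structural dependencies, skull indices, the 25-species / 16-genus sample
table, species-level element frequencies, and the fixed rooted topology
with labelled clades), simulators for Dollo-consistent character
histories, binomial specimen sampling and synthetic antler geometry, an
SVG renderer for diagrams, and a thin command-line wrapper
(`inst/scripts/antlerphy.R`).

## Worked example

```r
library(antlerphy)

# states coded at 85% and 40% observation frequency
code_state(c(85, 40))
#> [1] 2 1

# full pipeline on the packaged fixtures
rep <- run_pipeline()
rep$antlers[["Cervidae"]]
#> ancestral antler at node Cervidae — 2 point(s)
#>   B    brow tine (state 2)
#>   L    lower beam (state 2)

rep$antlers[["Cervini"]]$elements
#> [1] "B"   "L"   "T"   "H"   "BWP"
rep$antlers[["Capreolinae"]]$elements
#> [1] "B" "L" "F" "U"
c(rep$reconstructions[["T"]]$gain_edge, rep$reconstructions[["F"]]$gain_edge)
#> [1] "Cervini"     "Capreolinae"
```

Read: the most recent common ancestor of living deer carried a
two-pointed antler (brow tine + lower beam); the three-pointed antlers
of Cervini (trez tine + higher beam, plus a brow process) and of
Capreolinae (frontal tine + upper beam) are built from non-homologous
elements gained independently on the two clades' stem edges — the brow
process, being a process, adds no point.

Diagram geometry works the same way from code:

```r
a <- synthetic_antler(sim_config(seed = 7))
d <- build_diagram(a)
d$hierarchy          # nested fork parenthesisation
render_diagram(d, "antler.svg")
```

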