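# braidct

Braided circuit topology of multichain polymer systems.

Small aggregates of semiflexible polymers — four bead-spring chains is the
reference case — undergo a structural transition from amorphous globules to
aligned, possibly twisted bundles as the bending stiffness grows.  `braidct`
characterises that transition with two complementary topological
descriptions of a 3D multichain conformation:

* **Circuit topology (CT).**  Every pair of binary contacts (a contact is a
  bead pair within `r_c = 1.4 σ`, with intrachain pairs requiring backbone
  separation ≥ 3) is classified into one of nine motifs: `S`, `P`, `X`
  (series / parallel / cross on one chain), `I2`, `L2`, `T2` (two chains),
  `I3`, `T3` (three chains), `I4` (four chains).  The fraction of pairs in
  each class is an order parameter; the interchain sum `[L2]+[T3]+[I4]`
  reaches 1 exactly when all intrachain loops have vanished, i.e. when the
  aggregate has aligned.

* **Braid theory.**  Conformations are converted to words in the Artin
  braid group B_n by projecting the (primitive-path-contracted) chains
  onto a frame built from the chain endpoints and recording strand
  exchanges slice by slice.  Four invariants are computed through exact
  integer Dynnikov loop-coordinate dynamics:
  writhe `W = Σ_k sign(letter_k)`; minimal word length `L` (certified by
  search over the rewriting closure, compared via a total loop-coordinate
  invariant); the curve-diagram complexity
  `C = log(#βE / #E)` where `#βE` counts the taut intersections of the
  image of a canonical spanning curve with the real axis (`#E = n − 1`);
  and the Thurston–Nielsen isotopy class (finite-order / reducible /
  pseudo-Anosov) via central-power detection, invariant round multicurves,
  and the exponential-growth test.

A minimal Kremer–Grest simulator (FENE bonds `K = 30 ε/σ²`, `R0 = 1.5 σ`;
truncated shifted Lennard-Jones pairs; bending energy `κ k_B T (1 − cos θ)`;
BAOAB Langevin thermostat, `Δt = 0.01 τ`) and a primitive-path-analysis
minimizer are included, so the full pipeline — simulate, equilibrate,
contract, classify, braid — runs from a single seed.

## Worked example

```r
library(braidct)

# the worked 4-strand braid word
w <- parse_braid("2 -1 -3 1 1 2 -2", n = 4)
braid_invariants(w, log_base = exp(1))
#>   n writhe minimal_length complexity tn_class reduced_word
#> 1 4      1              3   1.609438       PA       2 1 -3
```

The seven-letter word has writhe 1 and reduces to three letters; its image
of the canonical spanning curve has five times as many axis intersections
per component as the initial diagram, so the natural-log complexity is
`ln 5 = 1.61`, and the loop-coordinate norm grows exponentially under
iteration, marking the braid pseudo-Anosov.

```r
# a desk-scale stiffness sweep (four chains of ten beads, T = 1, rho = 0.01)
sw <- run_sweep(kappas = c(0, 12), replicas = 4, seed = 1,
                block_tau = 150, max_tau = 600)
sw$summary$mean[, c("kappa", "CR", "inter_sum")]
#>   kappa        CR inter_sum
#> 1     0 0.2987197 0.5032486
#> 2    12 0.7974223 1.0000000
```

At `κ = 12` the chains form an aligned bundle: the end-to-end correlation
parameter `C_R = (2/M(M−1)) Σ_{i<j} (û_i · û_j)²` rises from its amorphous
value toward 1 and the interchain motif fractions sum to 1, i.e. every
contact pair is purely interchain.  `plot_sweep()` and
`plot_motif_fractions()` draw the order parameters against stiffness.

A thin command-line interface over the same functions is installed at
`inst/exec/braidct`, with subcommands `simulate`, `ppa`, `contacts`,
`extract`, `invariants`, `sweep` and `fixtures`, all reading and writing
plain-text LAMMPS-style dump files and TSV tables.

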