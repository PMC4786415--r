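# betalayer

Detection and analysis of **β-layers** — a triangular supersecondary
element inside trimeric α-helical coiled coils — for structural
bioinformaticians working on fibrous proteins (trimeric autotransporter
adhesin stalks, phage tail fibers, viral fusion stalks).

A parallel coiled coil absorbs insertions into its heptad repeat by
supercoiling: a repeat of *r* residues over *t* turns has local
periodicity *r/t* (residues per turn relative to the bundle axis),
confined to roughly 3.33–3.9 around the 3.63 residues/turn of an
unperturbed helix. Insertions of 2 residues (or 9 ≡ 2 mod 7) have no
accessible accommodation — 9/3 = 3.0 and 16/4 = 4.0 both fall outside
the band. Such insertions instead break helical structure locally: each
chain puts three residues into the β region of the Ramachandran plot
(−180 ≤ φ ≤ −40, 20 ≤ ψ ≤ 180), the three short strands cross in a
plane perpendicular to the bundle axis, the central strand residues form
cyclic cross-chain backbone hydrogen bonds (N–O ≤ 3.5 Å), and the path
of every chain moves ~120° around the trimer axis. The layer replaces a
core *d* position, giving the registers *a-b-c*-β₁β₂β₃-*e-f-g* (nonads)
and *e-f-g/c*-β₁β₂β₃-*e-f-g* (hexads, with the hybrid *g/c* position
displaced from ideal *g* toward *c*).

The package provides:

* the **two-step detector**: sliding-window scan for βββαααα / ααααβββ
  torsion patterns, then central-residue hydrogen-bond pairing within a
  biological assembly (`detect_beta_layers()`, with capping and
  transition annotation);
* **TWISTER-style local periodicity and Crick-angle analysis** with
  three-residue smoothing and heptad register assignment including the
  *g/c* position (`periodicity_trace()`, `assign_register()`);
* the **periodicity algebra** of insertions and their delocalization
  (`periodicity()`, `insertion_periodicity()`, `accommodation_report()`);
* **consensus motif scanning** over sequences: the core
  [aliphatic]-A-T-K-[polar]-[DE] and the tandem LxxKADKxxVYTKxE
  (`scan_consensus()`, `scan_tandem()`, `scan_fasta()`);
* a **synthetic structure generator**: Crick-parameterized coiled coils
  of chosen periodicity and planted, ground-truth-annotated β-layer
  fixtures (`generate_crick_coil()`, `generate_beta_layer_fixture()`);
* PDB/mmCIF input via bio3d with REMARK 350 assembly expansion
  (`read_structure()`, `select_assembly()`).

## Worked example

Generate a C3-symmetric bundle with a planted nonad β-layer, detect it,
and read off the register:

```r
library(betalayer)

fx <- generate_beta_layer_fixture("nonad")
layers <- detect_beta_layers(fx)
layers[[1]]
#> <beta_layer: 3 strand(s) (canonical), capping N-cap, transition cc-to-cc>
#>   A 15-17 MAT
#>   B 15-17 MAT
#>   C 15-17 MAT

trace <- periodicity_trace(fx$chains[[1]], bundle_axis_line(c(0,0,0), c(0,0,1)))
assign_register(trace, layers)[12:20]
#> [1] "a"     "b"     "c"     "beta1" "beta2" "beta3" "e"     "f"     "g"
```

One canonical (three-strand) layer is found on residues 15–17 of each
chain; the MAT strand (hydrophobic β₁) carries the N-capping interaction
network, the flanks are helical on both sides (`cc-to-cc`), and the
register around the layer reads *a-b-c*-β₁β₂β₃-*e-f-g* — the layer sits
in place of position *d*. The algebra shows why a 2-residue insertion
needs this element:

```r
accommodation_report(2)
#>   insert_length heptads residues turns periodicity handedness accessible
#> 1             2       1        9     3           3       left      FALSE
#> 2             2       2       16     4           4      right      FALSE
```

No delocalization up to two heptads reaches the accessible band
(`attr(..., "requires_beta_layer")` is `TRUE`).

The numbered scripts under `analysis/` run the full workflow — insertion
algebra, generator↔analyzer periodicity recovery, fixture detection with
registers, noise robustness, motif scans — writing tables under
`results/`.

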