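# ifdyn

Interface dynamics of protein–protein complexes from MD snapshots.

Protein–protein interfaces are usually described from a single crystal
structure, yet molecular-dynamics simulations show that an interface is a
dynamical object: residue contacts rearrange, the buried surface breathes,
and the interface can dwell in distinct long-lived **substates**. `ifdyn`
turns a trajectory of a two-chain complex (sampled into snapshots, typically
one per nanosecond) into a quantitative description of that dynamics. It is
aimed at structural bioinformaticians and simulators who want
interface-centric summaries of their trajectories without re-deriving the
bookkeeping every time.

## What it computes

**Contacts and their conservation.** A residue pair (one residue per chain)
is in contact when its minimal heavy-atom distance is ≤ 5 Å. Per snapshot
`t` the package reports the contact set `C_t`, the fraction of initial
contacts preserved, `|C_t ∩ C_ref| / |C_ref|`, the polar/apolar composition
of the contacts, and geometric hydrogen-bond counts (donor–acceptor ≤ 3.5 Å,
H–D–A angle ≤ 30° when hydrogens are present).

**Surface descriptors.** Shrake–Rupley solvent-accessible surface areas
(probe 1.4 Å) give the buried surface ΔASA = ASA_A + ASA_B − ASA_AB, Levy's
support/core/rim interface regions from relative ASA in the isolated-chain
and complex contexts (25% threshold), a SURFNET-style grid estimate of the
gap volume with the gap index `2·gap volume / ΔASA`, and a CAPRI-style
interface RMSD (backbone of residues within 10 Å of the partner, Kabsch
superposition).

**Substates.** Snapshot interfaces are compared with the Jaccard index
`J(C1, C2) = |C1 ∩ C2| / |C1 ∪ C2|` and clustered hierarchically (Ward.D2
on `1 − J`). Diagnostics — smallest/largest cluster size, number of cluster
changes in time, mean within-cluster dissimilarity — guide the choice of the
number of substates; each cluster is represented by its centroid (highest
mean Jaccard similarity to the other members) and the dissimilarities can be
projected to two principal coordinates.

**Per-substate contact statistics.** From the relative frequency `F_c(XY)`
of contact `XY` in cluster `c`, the package derives the across-cluster
variance per contact, the residue-level map
`var(X) = max_Y var(XY)`, and the recurrence index
`recurrence(X) = min_c max_Y F_c(XY)`, which separates residues engaged in
every substate from those that come and go. Scores can be cross-referenced
with single-mutation ΔΔG tables (hotspots: ΔΔG < −2.0 kcal/mol).

**Structural waters.** Hydration shells from the minimal water-oxygen to
heavy-atom distance (first shell < 3.4 Å, second 3.4–5.0 Å), the number of
waters released upon complexation
(`N_free A + N_free B − N_complex`, time-averaged), interfacial waters
(< 4 Å from both chains), water-mediated contacts
(residue–water–residue triplets, counted once per snapshot per pair), and
per-residue interfacial-water contact distributions by cluster.

**Statistics.** Pearson correlations (e.g. released waters vs binding
affinity) and the Dunn–Clark z test for comparing two dependent overlapping
correlation coefficients measured on the same complexes.

A synthetic-data module generates toy two-chain pseudo-atomic complexes with
explicit waters (bound and unbound forms) and contact-set time series with
hidden Markov-style substates and flip noise, providing ground truth for
every stage.

## Worked example

Two planted substates (30 contacts each, 15 shared), 150 + 150 snapshots,
5% contact flip noise:

```r
library(ifdyn)

s1 <- newContactSet(data.frame(chain1 = "A", resid1 = 1:30,
                               chain2 = "B", resid2 = 1:30))
s2 <- newContactSet(data.frame(chain1 = "A", resid1 = 16:45,
                               chain2 = "B", resid2 = 16:45))
sp  <- substateSpec(list(s1, s2),
                    data.frame(substate = c(1, 2), n = c(150, 150)),
                    flip_noise = 0.05, seed = 7)
out <- genContactSeries(sp)

J   <- jaccardMatrix(out$sets)
sug <- suggestNClusters(J, k_max = 6)
sug$diagnostics
#>  k min_size max_size n_changes intra_dissim
#>  1      300      300         0    0.3971433
#>  2      150      150         1    0.1364939
#>  3       15      150        29    0.1340806
#>  4       11      139        49    0.1328540
#>  5       11      139        77    0.1278830
#>  6       11      139        98    0.1256475
sug$recommended
#> [1] 2
```

Only `k = 2` combines well-populated clusters with stability in time (one
label change); larger k splinters off small, rapidly alternating clusters.

```r
cl <- clusterInterfaces(J, sug$recommended)
cl
#> InterfaceClustering: 300 snapshots in 2 clusters
#>   min size 150, max size 150, 1 changes along time
#>   centroid snapshots: 2, 155

ft <- contactFrequencies(out$sets, cl)
sc <- residueScores(ft)
head(sc[order(-sc$recurrence), ], 4)
#>  chain resid max_variance recurrence
#>      A    27 1.111111e-05  0.9666667
#>      B    27 1.111111e-05  0.9666667
#>      A    19 1.000000e-04  0.9600000
#>      A    25 1.000000e-04  0.9600000
```

The recovered labels match the planted ones exactly, and the
highest-recurrence residues (indices 16–30) are precisely those shared by
both substate contact sets — present at the interface in every cluster,
with near-zero frequency variance.

The full pipeline (contacts → geometry → clustering → substate statistics →
water → correlations) runs from one config:

```r
res <- runPipeline(list(seed = 1, output_dir = "run1",
                        input = list(synthetic = list(
                            n_residues = 6, n_waters = 15,
                            n_snapshots = 6, seed = 1))))
```

which writes `contacts.csv`, `geometry.csv`, `cluster_labels.csv`,
`residue_scores.csv`, `shell_counts.csv`, `water_bridges.csv`,
`summary.json` and a run log; identical config + seed gives byte-identical
outputs. Real trajectories enter through
`loadSeries(structure, trajectory, chains = c("A", "B"))` (multi-model PDB,
or PDB topology + DCD).

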