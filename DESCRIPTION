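Package: ifdyn
Title: Interface Dynamics of Protein-Protein Complexes from MD Snapshots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of protein-protein interfaces along molecular dynamics
    trajectories. Extracts cross-chain residue contacts from snapshots,
    measures their conservation and polar/apolar composition, computes
    solvent-accessible surface areas, buried surface (delta-ASA), Levy
    core/rim/support interface regions, gap volume and gap index, and
    interface RMSD. Snapshot interfaces are compared with the Jaccard index
    and clustered hierarchically (Ward.D2) into long-lived substates, with
    cluster diagnostics, centroid selection and principal-coordinate
    projections. Per-cluster contact frequencies yield residue-level variance
    and recurrence indices that can be cross-referenced with mutational
    hotspot data. Water analyses count hydration-shell waters, estimate
    waters released upon complexation, identify interfacial and bridging
    (water-mediated) contacts, and relate released waters to binding affinity
    through Pearson correlations and the Dunn-Clark test for dependent
    correlation coefficients. A synthetic-data module generates toy atomic
    complexes with explicit waters and substate-switching contact series with
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
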