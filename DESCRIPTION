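Package: parch
Title: PARCH Hydropathy Scale for Nucleic Acids and Nucleic Acid-Protein
    Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes per-residue hydropathy on the PARCH scale (Protocol for
    Assigning a Residue's Character on a Hydropathy scale) for DNA, RNA and
    their protein complexes. Each nucleotide is scored twice, once for its
    sugar-phosphate backbone (BB) and once for its nitrogenous base (NB),
    from the autocorrelation of the number of hydration-shell waters observed
    around the region during a restrained simulated-annealing trajectory,
    normalized against a zwitterionic-lysine reference and scaled by 10.
    Includes PDB parsing and B-factor annotation, hydration-shell and
    counterion system preparation, water counting with cell-list
    acceleration, radial distribution functions, population statistics
    (densities, per-type summaries, Kruskal-Wallis with Dunn post hoc,
    complex-versus-component deltas), and a seed-deterministic synthetic
    trajectory generator for desk-scale validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
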