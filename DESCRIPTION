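Package: plastevol
Title: Reductive Plastid Genome Evolution: Equilibrium AT Content,
    Selection Contrasts and Gene-Loss Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying reductive evolution of plastid genomes in
    heterotrophic plants. Detects the quadripartite plastome structure
    (inverted repeat and single-copy regions), classifies genes as intact,
    pseudogenized or absent, and maps gene losses on a phylogeny by Fitch
    and Dollo parsimony. Implements GTR+Gamma likelihood computation,
    marginal ancestral sequence reconstruction and ancestral indel
    reconstruction on a fixed topology, from which it estimates the
    equilibrium AT content of a sequence from strong-to-weak and
    weak-to-strong substitution counts with column-bootstrap confidence
    intervals, and summarizes synonymous substitution spectra in
    trinucleotide contexts. Also provides branch-model codon (dN/dS)
    likelihood fits with likelihood-ratio tests and false-discovery-rate
    control, amino-acid composition bias statistics, and single- versus
    two-regime Ornstein-Uhlenbeck tests for shifts in continuous traits on
    a phylogeny. Seed-deterministic simulators for nucleotide, codon,
    trait and gene-loss evolution, and for toy quadripartite genomes,
    allow every stage to be exercised end to end on synthetic data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
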