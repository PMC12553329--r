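Package: protzoo
Title: Uniform Fit-Transform-Score Models for Protein Variant Effect Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale model zoo for protein property prediction under a
    single estimator contract. Provides validated protein sequence, alignment
    and mutation data types with FASTA/A2M input and output, saturation
    mutagenesis library generation, minimal PDB chain extraction, a uniform
    init-fit-transform-score lifecycle with declared model capabilities
    (needs-MSA, needs-structure, needs-wild-type) and automatic remediation,
    lightweight embedders (fixed-length one-hot, MSA-aligned one-hot with
    align-to-profile, k-mer counts), an independent-sites column-frequency
    zero-shot scorer, masked/wild-type/mutant marginal scoring over pluggable
    conditional sequence models, a capability-aware model registry, synthetic
    alignment-family generators for fully offline testing, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
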