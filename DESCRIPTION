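Package: modelcritic
Title: Model Quality Assessment for Predicted Protein Tertiary Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A model-quality-assessment toolkit in the style of the CASP
    tertiary-structure evaluations. Implements a panel of superposition-based
    and superposition-free structural metrics (GDT_TS/GDT_HA, LDDT,
    Sphere-Grinder, a contact-area-difference surrogate, DipDiff, a clash
    surrogate, backbone and side-chain dihedral deviations, side-chain
    chi-angle accuracy, self-assessment accuracy), a two-round z-score
    tournament ranking with a weighted composite score, local-error region
    detection with crystal-lattice and chain-interface context, B-factor
    error binning, molecular-replacement model preparation (confidence
    trimming, coordinate-based rigid splitting, LLG points ranking),
    catalytic-site RMSD with chemical-equivalence handling, and a synthetic
    model/target generator so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
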