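Package: lyaseprofile
Title: Charged-Residue, Salt-Bridge and Motif Profiling of MIO Ammonia-Lyases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Comparative sequence and structure descriptors used to
    rationalize thermotolerance and alkalophilicity in the MIO-dependent
    aromatic amino acid ammonia-lyase family (PAL, HAL, TAL): per-chain
    ionizable-residue composition and acid excess, motif-based family
    classification anchored on the Ser-His selectivity dyad and the
    MIO-forming Ala-Ser-Gly tripeptide, salt-bridge detection on multimeric
    assemblies under a side-chain oxygen-nitrogen distance criterion with
    count-once participation statistics, disulfide-candidate detection
    between cysteines with intra/inter-subunit classification, and an
    exposure-weighted surface-charge descriptor built on Shrake-Rupley
    solvent-accessible surface areas. Includes a synthetic-structure and
    synthetic-sequence generator with certified planted ground truth so the
    whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
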