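Package: archaeproteo
Title: Comparative Proteome Profiling of Archaea
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative proteome analysis of archaea and other
    prokaryotes: relative amino-acid usage profiles (full and GC-unbiased
    reductions), physico-chemical indices per protein (isoelectric point,
    GRAVY, aromaticity, aliphatic and instability indices) and their binned
    distributions, complete-linkage clustering and correspondence analysis
    of compositional tables, directional amino-acid substitution-bias
    statistics between ortholog sets, and COG repertoire set analysis
    (category profiles, core and exclusive COGs, four-way Venn partitions).
    Includes a deterministic synthetic-data generator (GC-driven proteomes,
    bias-injected ortholog pairs, planted COG universes) so the whole
    pipeline can be exercised without genome downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
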