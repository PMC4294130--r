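Package: plastidpoly
Title: Plastid Genome Structure, Repeats, Diversity and Heteroplasmy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing complete chloroplast (plastid) genomes and
    their within-species polymorphism. Detects the quadripartite
    LSC/IRa/SSC/IRb structure from raw sequence and fixes a canonical
    rotation; scans for perfect microsatellites (SSRs) and long tandem
    repeats; partitions two genomes into exon-anchored orthologous fragments
    and computes region-wise nucleotide diversity and Nei-Gojobori (1986)
    Ka/Ks with Jukes-Cantor correction; calls variants between two
    near-identical plastomes; profiles heteroplasmic minor-allele sites from
    read pileups across strains; and clusters strains by UPGMA on
    minor-allele-frequency profiles. A synthetic-data generator with
    recorded ground truth makes every stage testable without external
    sequence downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
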