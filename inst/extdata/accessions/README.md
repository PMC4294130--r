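# Optional accession data

The cross-accession checks in the test suite run against real chloroplast
genome sequences that are **not** shipped with the package (they are
~156 kb each and must be fetched from GenBank). To enable them, download
the following records as plain FASTA and place them in this directory
before installing, named exactly:

- `KC686331.fa` — *Panax ginseng* strain Damaya (DMY) chloroplast
- `KF431956.fa` — *Panax ginseng* strain Yeshanshen (YSS) chloroplast
- `NC_006290.fa` — *Panax schinseng* Nees chloroplast

e.g. via NCBI EFetch:

    https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi?db=nuccore&id=KC686331&rettype=fasta&retmode=text

Without these files the corresponding acceptance test reports failure —
every other test in the suite is self-contained and runs on synthetic
data generated in code.
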