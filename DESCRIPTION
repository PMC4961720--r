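Package: pepscan
Title: Glycine-Scanning Design and NMR Chemical-Shift Analysis of
    Antimicrobial Peptides
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Physicochemical descriptor panel for short antimicrobial
    peptides (Boman protein-binding index, Kyte-Doolittle GRAVY,
    Wimley-White whole-residue interface partitioning, net charge,
    hydrophobic ratio, average molecular mass), in-silico glycine-scanning
    mutagenesis with reactive-position ranking and exhaustive charged
    substitution design, and NMR conformational analysis from assigned
    proton chemical shifts: alpha-CH chemical-shift deviations from random
    coil, helix/coil classification, and NOE distance-restraint category
    accounting.  Includes seeded generators for synthetic peptides, shift
    tables and restraint lists, plain-text readers and writers for FASTA,
    shift-table TSV and CYANA-style UPL formats, and a command-line
    entry point.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'scales.R'
    'peptide.R'
    'shift_table.R'
    'restraints.R'
    'csd.R'
    'synthetic.R'
    'descriptors.R'
    'scan.R'
    'design.R'
    'cli.R'
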