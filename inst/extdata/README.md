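# External data

`dataset_s2.faa` (not shipped): the 366 SbmA/BacA-like protein sequences
deposited as supplementary Dataset S2 of the study this package's replication
checks refer to (doi:10.1099/mgen.0.001380). Place the FASTA file here (or in
the installed package's `extdata/` directory) to enable the replication test
in `tests/testthat/test-acceptance.R` and the corresponding section of
`scripts/acceptance.R`, which rebuild the sequence similarity network at
alignment score 115 and compare component sizes against the published
clusters. The file cannot be redistributed with the package and is never
downloaded automatically.

Everything else the tests need (proteomes, seeds, species tables, trees) is
generated in code by the synthetic benchmark module.
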