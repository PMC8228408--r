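Placeholder for externally obtained chronology tables.

The correlation and MA-law tables for tRNA, 5S rRNA, RNase P RNA and rRNA
were computed from published data matrices and rooted trees of substructures
that are not redistributable here. To reproduce them, transcribe each
molecule type's substructure chronology into a TSV with columns

    label  class  nd  mean_length

(one row per substructure; class is "helical" or "unpaired"; nd the relative
node-distance age in [0, 1]; mean_length the average length over taxa,
absences excluded) and save it in this directory as

    tRNA_helical.tsv  5S_rRNA_helical.tsv  RNaseP_helical.tsv  rRNA_helical.tsv

The test suite (tests/testthat/test-acceptance.R) then recomputes the
regression slopes and MA-law fits with read_series(), correlate() and
fit_ma_special() and compares them with the reported values.
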