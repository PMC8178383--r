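Packaged reference tables (plain TSV, tab-separated, UTF-8)
===========================================================

These fixtures are hand transcriptions of the summary tables of a published
durum wheat meta-QTL study (41 literature QTL studies projected onto the
Maccaferri consensus map). The underlying per-study QTL database is not
publicly deposited; only these summary tables are reproducible inputs.

trait_dictionary.tsv   36 trait codes grouped into quality / abiotic /
                       biotic stress categories; the package's default
                       trait vocabulary.

study_populations.tsv  Mapping populations behind the QTL database, one row
                       per (cross, trait): population type (RIL/DH/BC/BIL/BP),
                       size, and the number of QTL reported for that trait.

mqtl_catalogue.tsv     The 85-row meta-QTL catalogue: consensus peak (cM),
                       member-QTL count, trait set, 95% CI bounds (cM) and
                       the closest flanking markers with physical positions
                       (bp). Marker names and bp positions were concatenated
                       without a delimiter in the source rendering; the split
                       applied here is calibrated so that the flanking-marker
                       distances of the ten selected MQTL reproduce the
                       published Mb distances (selected_mqtl.tsv). Note: this
                       table contains 27 two-member MQTL while the source's
                       prose says 26; the transcription follows the table.

selected_mqtl.tsv      The 10 promising MQTL passing the Löffler-style
                       selection (n_qtl >= 5, CI <= mean CI, mean PVE >= 0.10)
                       plus the < 5 Mb physical filter, with CI width (cM),
                       flanking-marker distance (Mb) and mean PVE.

genes per MQTL
mqtl_gene_counts.tsv   Gene-model counts within the selected MQTL intervals
                       after excluding transposable elements, for the durum
                       (Svevo) and bread wheat (Chinese Spring) annotations.
                       The durum column sums to 456 although the source text
                       prints a total of 436; the discrepancy is deliberate
                       and flagged, not corrected.
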