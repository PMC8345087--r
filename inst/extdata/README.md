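# Bundled demo data

`snp_manifest_synthetic.tsv` — a 22-SNP design manifest for demos and tests.
rs10514231 (risk T / protective C) and rs2089222 are real rsIDs of breast
cancer risk SNPs in autophagy-gene regions; their flanking contexts here,
the rs2089222 alleles, and the 20 `rsSIM*` entries are synthetic
placeholders generated for this package, not genomic sequence. Columns:
rsid, risk_allele, protective_allele, context, snp_offset (0-based index of
the SNP in context), source.
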