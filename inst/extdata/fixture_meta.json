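{
  "description": "Packaged worked example: four discordant sib pairs (never-smoker early-onset lung adenocarcinoma patients and their unaffected sibs). Candidate variants transcribed from the published per-case variant table; genomic coordinates, read depths, background variants, interaction edges and FPKM values are SYNTHETIC, constructed so that the documented default thresholds reproduce the published summary counts.",
  "synthetic_fields": ["chrom", "pos", "ref", "alt", "depth", "allele depths", "maf", "cadd_phred", "metasvm", "FPKM values", "interaction edges", "background variants"],
  "n_pairs": 4,
  "n_candidate_variants": 40,
  "shared_variants": ["CARS c.G775A (cases 2 and 3)", "ESRRA c.C1162T (cases 3 and 4)", "ESRRA c.C1165T (cases 3 and 4)"],
  "rna_effect_panel": 17,
  "expression_classes": {"TUMOR_DOWN": 8, "TUMOR_UP": 3, "BOTH_DOWN": 5},
  "retained_no_change": ["URI1"],
  "n_loh": 9,
  "loh_note": "The identities of the nine LOH genes are not printed in the source; events are planted among the downregulated RNA-effect variants (8 TUMOR_DOWN + IQGAP2).",
  "transcription_notes": [
    "The running text assigns the shared ANGPTL4 and ESRRA variants to cases 1 and 4 and CARS to cases 3 and 4; the table checkmarks place ANGPTL4 in case 3 only, ESRRA in cases 3 and 4, and CARS in cases 2 and 3. This transcription follows the table checkmarks.",
    "The extracted table text carries one case-4 row more than the printed total of 40 variants and the checkmark-derived per-case counts (6/14/13/10) support; the FAM188A row (deprecated symbol, now MINDY3) was treated as an extraction artifact and omitted.",
    "Under the checkmark case assignments the five-gene interaction network (EPHB6, ACACA, ENO3, CARS, ACAP2) spans cases 1-3; the running text's case attribution would span all four cases."
  ]
}
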