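# Development-and-validation cohort: 167 samples over 17 genotypes, with the
# (HBA1, HBA2) copy pair each genotype presents to the assay. n_pcr1 = samples
# pre-genotyped by the commercial strip assay; n_pcr2 = prospective samples.
- {genotype: "aa/aa (wild type)", hba1: 2, hba2: 2, n_pcr1: 30, n_pcr2: 24}
- {genotype: "aa/-a3.7",          hba1: 2, hba2: 1, n_pcr1: 29, n_pcr2: 19}
- {genotype: "-a3.7/-a3.7",       hba1: 2, hba2: 0, n_pcr1: 20, n_pcr2: 16}
- {genotype: "aa/-a4.2",          hba1: 2, hba2: 1, n_pcr1: 2,  n_pcr2: 0}
- {genotype: "-a4.2/-a4.2",       hba1: 2, hba2: 0, n_pcr1: 1,  n_pcr2: 0}
- {genotype: "-a3.7/-a4.2",       hba1: 2, hba2: 0, n_pcr1: 3,  n_pcr2: 0}
- {genotype: "-a3.7/--SEA",       hba1: 1, hba2: 0, n_pcr1: 3,  n_pcr2: 3}
- {genotype: "aa/--MED",          hba1: 1, hba2: 1, n_pcr1: 2,  n_pcr2: 0}
- {genotype: "aa/--FIL",          hba1: 1, hba2: 1, n_pcr1: 2,  n_pcr2: 0}
- {genotype: "-(a)20.5",          hba1: 2, hba2: 1, n_pcr1: 1,  n_pcr2: 0}
- {genotype: "aa/aaa-anti3.7",    hba1: 2, hba2: 3, n_pcr1: 2,  n_pcr2: 0}
- {genotype: "-a3.7/a-Icaria-a",  hba1: 2, hba2: 1, n_pcr1: 1,  n_pcr2: 0}
- {genotype: "aa/a-polyA1-a",     hba1: 2, hba2: 2, n_pcr1: 2,  n_pcr2: 0}
- {genotype: "aa/a-polyA2-a",     hba1: 2, hba2: 2, n_pcr1: 1,  n_pcr2: 0}
- {genotype: "-a3.7/a-polyA1-a",  hba1: 2, hba2: 1, n_pcr1: 4,  n_pcr2: 0}
- {genotype: "aa/a-CS-a",         hba1: 2, hba2: 2, n_pcr1: 1,  n_pcr2: 0}
- {genotype: "a-CS-a/a-CS-a",     hba1: 2, hba2: 2, n_pcr1: 1,  n_pcr2: 0}
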