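# End-to-end run over the published summary associations: positive
# controls (RA, CHD), downstream biomarkers (CRP, fibrinogen), and the
# NAFLD meta-analysis from published per-cohort odds ratios. Files
# involving rs10752641 carry invented placeholder alleles/LD (its real
# values were never published); it is removed as palindromic anyway.
exposure:
  file: il6_candidates_synthetic.tsv
  label: IL-6 GWAS
  trait: IL-6
  trait_type: quantitative
  n: 30000
  column_map:
    rsid: SNP
    effect_allele: A1
    other_allele: A2
    eaf: EAF
    beta: BETA
    se: SE
    pvalue: P
outcomes:
  - file: outcome_ra.tsv
    label: RA GWAS
    trait: RA
    trait_type: binary
  - file: outcome_chd.tsv
    label: CHD GWAS
    trait: CHD
    trait_type: binary
  - file: outcome_crp.tsv
    label: UK Biobank CRP
    trait: CRP
    trait_type: quantitative
    n: 361194
  - file: outcome_fibrinogen.tsv
    label: UK Biobank fibrinogen
    trait: fibrinogen
    trait_type: quantitative
    n: 361194
ld_file: ld_synthetic.tsv
external_estimates_file: nafld_cohort_or.tsv
criteria:
  p_max: 5.0e-8
  maf_min: 0.01
  ld_r2_max: 0.3
  drop_palindromic: true
se_method: first_order
ci_level: 0.95
primary_instrument: rs2228145
report_per_snp: true
meta_model: auto
power_scenarios:
  - label: non-FinnGen
    n: 19264
    case_fraction: 0.0770
    or_per_sd: 1.99
    r2_from: [rs2228145]
  - label: non-FinnGen-2snp
    n: 19264
    case_fraction: 0.0770
    or_per_sd: 1.99
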