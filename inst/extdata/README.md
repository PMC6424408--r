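# Packaged fixtures

- `validation_cohort_synthetic.tsv` — a 22-animal validation cohort
  (8 affected, all homozygous for the risk allele; 14 unaffected,
  heterozygous or homozygous wild-type) mirroring the published cohort
  composition. The per-animal het/hom-ref split among the unaffected is
  synthetic: only the composition, not per-animal genotypes, is public.
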