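# Toy end-to-end configuration: 2 chromosomes, 200 markers, one planted
# QTL cluster (2 traits x 2 years) on chr1 at 30 cM.
seed: 42
simulate:
  n_accessions: 200
  n_subpops: 4
  fst: 0.2
  n_chromosomes: 2
  markers_per_chrom: 100
  map_length_cm: 150
  chrom_length_bp: 600000000
  ld_decay_cm: 5
  planted_qtls:
    - {chrom: chr1, cm: 30, trait: yield, effect: 0.12}
    - {chrom: chr1, cm: 30, trait: height, effect: 0.12}
  h2_targets: {yield: 0.2, height: 0.2}
  years: ["2017", "2018"]
  missing_rate: 0.02
gwas:
  n_pcs: 4
hotspots:
  high_mult: 5
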