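seed: 42
panel:
  n_genes: 15
  spikeins: true
treatments: [keep_all, rm_se, rm_pe]
libraries:
  - name: truseq_a
    protocol: truseq
    target_depth: 8000
    gene_molecules: 60
    spikein_top_molecules: 300
  - name: truseq_b
    protocol: truseq
    target_depth: 8000
    gene_molecules: 60
    spikein_top_molecules: 300
  - name: truseq_c
    protocol: truseq
    target_depth: 8000
    gene_molecules: 60
    spikein_top_molecules: 300
power:
  n_per_group: [3]
  n_sims: 2
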