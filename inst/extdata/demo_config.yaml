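# Demo pipeline configuration: small synthetic run on the nine-species
# framework tree. All stages; a few minutes on one CPU.
seed: 1
outdir: chemevolve_demo_out
n_families: 4
n_codons: 120
dup_rate: 0.3
loss_rate: 0.1
pseudo_rate: 0.15
stages:
  - simulate
  - annotate
  - divergence
  - trees
  - reconcile
  - selection
  - report
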