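# Simulated five-level overlap analysis at default world scale.
# Run with: run_pipeline(system.file("extdata/demo_config.yaml",
#                                    package = "gwasoverlap"))
seed: 7
simulate:
  world:
    n_genes: 200
    n_snps: 5000
  study:
    k: 5
    n_sig: 100
    theta_func_share: 0.5
    theta_snp_share: 0.5
    noise_frac: 0.2
perm:
  n_perm: 200
  n_perm_network: 40
out_dir: overlap_report
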