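# Default configuration. Every value here mirrors a function default; a user
# file only needs the keys it overrides.
seed: 1

enzyme:
  name: XhoI
  motif: CTCGAG
  cut_offset: 1          # XhoI cleaves C^TCGAG, one base into the motif

scoring:                 # optical-map alignment (see om_scoring_params)
  sizing_sd_per_kb: 0.1  # sizing noise scale, kb per sqrt-kb (in-silico maps)
  missed_cut_penalty: 3  # per merged reference fragment
  false_cut_penalty: 3   # per merged query fragment
  match_score: 5         # per-block bonus; true alignments score > 0
  max_block_span: 4      # max fragments merged on either side of a block
  min_s_score: 0         # no minimum quality: every placeable contig is used

coloring:                # read coloring (see coloring_options)
  selection_mode: only_best
  match_fraction: 0.8    # matching bases must reach 80% of the read length
  extend_tails: true     # widen the contig interval by unaligned read tails
  adjust_colors: true    # remove gaps in the used colors
  min_s_score: 0

guidance:                # guided assembly (see guidance_params)
  max_color_step: 1      # consistent edge: color equal or exactly one greater
  propagation_limit: 0   # 0 = propagation disabled; 5 mirrors the guided
                         # assembler's own default
  min_overlap_bp: 1000
  min_overlap_fraction: 0
  reduce_fuzz: 100       # length slack for transitive-edge removal
  max_overhang: 1000
  overhang_ratio: 0.8

simulation:              # synthetic data (see simulation_config)
  n_chromosomes: 2
  chromosome_length: 150000
  site_density: 0.0001   # one planted XhoI site per 10 kb
  coverage: 40
  read_length_mean: 8200
  read_length_sd: 3000
  error_mismatch: 0.003
  error_insertion: 0.001
  error_deletion: 0.001
  map_sizing_sd: 0       # noise-free maps reproduce the error-free setting
  map_missing_cut_prob: 0
  map_false_cut_per_kb: 0
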