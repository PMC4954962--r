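# Example pipeline configuration: simulate a small screen end to end.
out_dir = "screen_run"

[simulate]
seed = 1
n_strains = 6          # mutants; a WT reference strain is always added
replicates = 3
noise_sd = 10          # grayscale units of camera noise
fields_per_well = 1
wt_inclusion_prob = 0.4
n_confounded = 2       # mutants rendered at reduced expression
confounded_scale = 0.5

[quantify]
cell_delta = 300       # cell isolation: >= 300 units over background
inclusion_delta = 400  # inclusion isolation: >= 400 units over cell level
min_cells_for_scoring = 30
shade_model = "poly2"

[hits]
wt_strain = "WT_his3"
alpha = 0.05
min_effect = 25
effect_mode = "relative_to_wt"
intensity = "diffuse"  # punctum-excluded expression proxy ("mean" = whole cell)

[enrich]
correction = "bonferroni"

[growth]
window_points = 9      # 4 h sliding window at 0.5 h sampling
blank = 0
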