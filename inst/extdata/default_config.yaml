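# Default pipeline configuration. Every field is validated on load and
# unknown keys are rejected.
classes: [running, aerobics, table_tennis]
sequences_per_class: 60
n_frames: 40
fps: 20
grid_w: 64
grid_h: 64
sigma: 3
limb_width: 2
noise_sd: 1
assemble: true
peak_threshold: 0.1
nms_radius: null        # null = sigma
e_min: 0.5
n_samples: 10
degree: 5
pca_precision: 0.95
pca_mode: standard
train_fraction: 0.7
stratified: true
svm_kernel: radial
svm_cost: 1
svm_gamma: null         # null = 1 / (d * mean feature variance)
classes_file: null      # null = shipped activity_classes.yaml
seed: 1
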