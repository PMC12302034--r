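num_classes: 4
image_size: 224
learning_rate: 0.01
adam_beta1: 0.8
adam_beta2: 0.999
weight_decay: 0.0005
temperature: 4.0
batch_size: 64
epochs: 300
train_frac: 0.7
seed: 1
w_epkt: 1.0
w_fce: 1.0
literal_total: no
mixup:
  alpha: 0.2
  factor: 4
  seed: 1
  include_originals: yes
  within_class: no
cnn:
  base: 64
  blocks:
  - 3
  - 4
  - 6
  - 3
  tap_stage: 3
mvt:
  patch: 16
  view_dims:
  - 256
  - 384
  - 512
  layers_per_view: 4
  global_depth: 4
  heads: 8
  mlp_ratio: 4
  tap_layer: 3
  multi_view: yes
checkpoint_every: 0
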