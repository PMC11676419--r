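# Default configuration: calibrated flagship architecture and published
# training hyper-parameters.
model:
  variant: transformer_dil_denseunet
  stem_width: 224
  growth: 24
  dense_layers: 4
  dilated_channels: 100
  compression: 0.5
  heads: 3
  d_ff: 2960
  patch_schedule: [1, 2, 4]
  dropout: 0.2
  input_channels: 1
  norm_placement: post
train:
  loss: bce_dice
  epochs: 100
  batch_size: 8
  learning_rate: 1.0e-4
  seed: 1
  threshold: 0.5
preprocess:
  target: 192
  fg_threshold: 0.02
  augment_factor: 3
  train_frac: 0.8
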