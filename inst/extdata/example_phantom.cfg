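# Example phantom configuration for `meniscus3d_cli("phantom", ...)`.
# Flat key = value pairs; unlisted keys keep the package defaults
# (a normal adult knee at 0.35 x 0.35 x 0.7 mm voxels).

# discoid lateral meniscus preset (dlm = 1 swaps in dlm_lateral_shape())
dlm = 1
lateral.coverage = 0.9
lateral.r_out_ap = 15.6

# crop the simulated field of view to speed generation up
field_mm = 100,70,20

# smooth radial segmentation-noise amplitude (mm, sd)
jitter_mm = 0.3
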