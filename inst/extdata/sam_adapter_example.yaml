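# Example adapter configuration recording the upstream mask generator's
# settings for provenance. The adapter itself is not executed by this
# package; see ?writeSamAdapterConfig.
adapter: sam
executed_by_this_package: no
points_per_side: 32
pred_iou_thresh: 0.95
stability_score_thresh: 0.95
min_mask_region_area: 1500
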