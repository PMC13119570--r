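# Stage-inversion ablation: each stage is routed to the other stage's
# segmenter and receives the other stage's prompt style.
detector_id: mock
segmenter_id_early: perturb_late
segmenter_id_late: perturb_early
detect_resize: 640
segment_resize: 1024
confidence_min: 0.25
aar_tolerance: 0.05
prompts: inverted
postprocess:
  largest_component: true
  fill_holes: false
  min_component_px: 16
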