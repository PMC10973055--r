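{
  "name": "M2CAI-tool (10/-/5 split)",
  "comment": "Configuration skeleton for the M2CAI 2016 tool-presence dataset (15 cholecystectomy videos, binary instrument annotations at 1 fps, no phase annotations). Annotation files are an external download and are NOT shipped. proposed_moves documents the published improvement: swapping surgeries 6 and 14 redistributes the heavily imbalanced Grasper+Irrigator+SpecimenBag and Bipolar+Irrigator combinations across train and test.",
  "phases": [],
  "instruments": [
    "Grasper",
    "Bipolar",
    "Hook",
    "Scissors",
    "Clipper",
    "Irrigator",
    "SpecimenBag"
  ],
  "phase_fps": 1,
  "instrument_fps": 1,
  "idle_phase_label": null,
  "split": {
    "train": ["tool_video_01","tool_video_02","tool_video_03","tool_video_04","tool_video_05","tool_video_06","tool_video_07","tool_video_08","tool_video_09","tool_video_10"],
    "val": [],
    "test": ["tool_video_11","tool_video_12","tool_video_13","tool_video_14","tool_video_15"]
  },
  "proposed_moves": [
    {"surgery_id": "tool_video_06", "to": "test"},
    {"surgery_id": "tool_video_14", "to": "train"}
  ]
}
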