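{
  "name": "Cholec80 (40/-/40 split)",
  "comment": "Configuration skeleton for the public Cholec80 laparoscopic cholecystectomy dataset. Annotation files are an external download and are NOT shipped with this package; point load_dataset() at a directory containing videoNN-phase.txt / videoNN-tool.txt. The 40/-/40 split assigns videos 1-40 to training and 41-80 to testing. proposed_moves documents the published re-assignment that brings the skipped-first-phase and late-cleaning-coagulation workflows into the test set while retaining the 40/-/40 shape.",
  "phases": [
    "Preparation",
    "CalotTriangleDissection",
    "ClippingCutting",
    "GallbladderDissection",
    "GallbladderPackaging",
    "CleaningCoagulation",
    "GallbladderRetraction"
  ],
  "instruments": [
    "Grasper",
    "Bipolar",
    "Hook",
    "Scissors",
    "Clipper",
    "Irrigator",
    "SpecimenBag"
  ],
  "phase_fps": 25,
  "instrument_fps": 1,
  "idle_phase_label": null,
  "split": {
    "train": ["video01","video02","video03","video04","video05","video06","video07","video08","video09","video10","video11","video12","video13","video14","video15","video16","video17","video18","video19","video20","video21","video22","video23","video24","video25","video26","video27","video28","video29","video30","video31","video32","video33","video34","video35","video36","video37","video38","video39","video40"],
    "val": [],
    "test": ["video41","video42","video43","video44","video45","video46","video47","video48","video49","video50","video51","video52","video53","video54","video55","video56","video57","video58","video59","video60","video61","video62","video63","video64","video65","video66","video67","video68","video69","video70","video71","video72","video73","video74","video75","video76","video77","video78","video79","video80"]
  },
  "proposed_moves": [
    {"surgery_id": "video29", "to": "test"},
    {"surgery_id": "video32", "to": "test"},
    {"surgery_id": "video33", "to": "test"},
    {"surgery_id": "video38", "to": "test"},
    {"surgery_id": "video58", "to": "train"},
    {"surgery_id": "video66", "to": "train"},
    {"surgery_id": "video71", "to": "train"},
    {"surgery_id": "video78", "to": "train"}
  ]
}
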