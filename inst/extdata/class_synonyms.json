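{
  "dysplastic_epithelial": "dysplastic_epithelial",
  "dysplastic": "dysplastic_epithelial",
  "dysplastic epithelial": "dysplastic_epithelial",
  "dysplasia": "dysplastic_epithelial",
  "atypical epithelial": "dysplastic_epithelial",
  "normal_epithelial": "normal_epithelial",
  "epithelial": "normal_epithelial",
  "normal epithelial": "normal_epithelial",
  "epithelium": "normal_epithelial",
  "basal": "normal_epithelial",
  "other": "other",
  "lymphocyte": "other",
  "inflammatory": "other",
  "immune": "other",
  "connective": "other",
  "stroma": "other",
  "stromal": "other",
  "fibroblast": "other",
  "endothelial": "other"
}
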