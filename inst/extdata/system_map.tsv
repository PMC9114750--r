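cancer_type	system
Colorectal	Digestive tract cancer
Liver	Digestive tract cancer
Esophageal	Digestive tract cancer
Gastric	Digestive tract cancer
Pancreatic	Digestive tract cancer
Cervical	Gynecological tumor
Lymphoma	Hematological tumors
Leukemia	Hematological tumors
Bone	Orthopedic tumor
Myeloma	Orthopedic tumor
Bladder	Tumor of urinary tract
Renal	Tumor of urinary tract
Prostate	Tumor of urinary tract
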