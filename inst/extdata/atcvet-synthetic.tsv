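product_or_substance	group
Vaccamune DHP	Immunologicals
Felivac Trio	Immunologicals
Parashield Spot-On	Antiparasitic products, insecticides and repellents
Wormexol Tablets	Antiparasitic products, insecticides and repellents
Thyronorm Drops	Systemic hormonal preparations
Flexicam Oral	Musculoskeletal system
Cardiopril 5mg	Cardiovascular system
Clavubactin 250	Antiinfectives for systemic use
Calmexin Gel	Nervous system
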