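product	listed_term
Vaccamune DHP	lethargy
Vaccamune DHP	injection site swelling
Vaccamune DHP	pyrexia
Vaccamune DHP	vomiting
Felivac Trio	lethargy
Felivac Trio	injection site swelling
Felivac Trio	pyrexia
Parashield Spot-On	pruritus
Parashield Spot-On	urticaria
Wormexol Tablets	vomiting
Wormexol Tablets	diarrhoea
Thyronorm Drops	vomiting
Thyronorm Drops	anorexia
Flexicam Oral	vomiting
Flexicam Oral	diarrhoea
Flexicam Oral	anorexia
Clavubactin 250	vomiting
Clavubactin 250	diarrhoea
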