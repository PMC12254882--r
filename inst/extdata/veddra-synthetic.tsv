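term	llt_code	llt_name	soc
vomiting	SYN-0001	Vomiting	Digestive tract disorders
lethargy	SYN-0002	Lethargy	Systemic disorders
injection site swelling	SYN-0003	Injection site swelling	Application site disorders
pruritus	SYN-0004	Pruritus	Skin and appendages disorders
diarrhoea	SYN-0005	Diarrhoea	Digestive tract disorders
anorexia	SYN-0006	Anorexia	Systemic disorders
seizure	SYN-0007	Seizure	Neurological disorders
ataxia	SYN-0008	Ataxia	Neurological disorders
urticaria	SYN-0009	Urticaria	Skin and appendages disorders
pyrexia	SYN-0010	Pyrexia	Systemic disorders
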