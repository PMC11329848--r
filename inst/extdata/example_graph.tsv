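TaiYang	Contain	WindCold	original
TaiYang	Contain	ExteriorDeficiency	original
YangMing	Contain	InteriorHeat	original
YangMing	Contain	Dryness	original
JueYin	Contain	ColdLimit	original
JueYin	Contain	UpperHeat	original
TaiYang	Manifest	fever	original
TaiYang	Manifest	aversion to wind	original
YangMing	Manifest	thirst	original
YangMing	Manifest	constipation	original
JueYin	Manifest	cold limbs	original
fever	CorrespondTo	WindCold	original
aversion to wind	CorrespondTo	ExteriorDeficiency	original
thirst	CorrespondTo	InteriorHeat	original
constipation	CorrespondTo	Dryness	original
cold limbs	CorrespondTo	ColdLimit	original
spontaneous sweating	CorrespondTo	ExteriorDeficiency	original
Cassia Twig Decoction	Treat	TaiYang	original
White Tiger Decoction	Treat	YangMing	original
Fructus Mume Pill	Treat	JueYin	original
Fructus Mume Pill	ContraindicationIs	JueYin	original
TaiYang	DifferentialDiagnosisIs	JueYin	original
Cassia Twig Decoction Syndrome	Manifest	shivering	original
YangMing	DifferentialDiagnosisIs	TaiYang	original
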