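name	delta	residues	terminus
carbamylation	43.005814	K	none
oxidation	15.994915	MW	none
acetylation	42.010565	K	none
phosphorylation	79.966331	STY	none
methylation	14.01565	KR	none
dimethylation	28.0313	KR	none
trimethylation	42.04695	K	none
deamidation	0.984016	NQ	none
formylation	27.994915	K	none
carbamidomethylation	57.021464	C	none
hexnac	203.079373	NST	none
hexose	162.052824	ST	none
glygly	114.042927	K	none
succinylation	100.016044	K	none
malonylation	86.000394	K	none
crotonylation	68.026215	K	none
propionylation	56.026215	K	none
butyrylation	70.041865	K	none
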