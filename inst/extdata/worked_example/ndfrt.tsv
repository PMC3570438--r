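N0000190001	Live Attenuated Bacillus Calmette-Guerin Vaccine [EPC]			
N0000190002	Live Attenuated Intravesical Bacillus Calmette-Guerin Vaccine [EPC]			
N0000190101	Actively Acquired Immunity [PE]			
N0000190102	Increased Macrophage Proliferation [PE]			
N0000190103	Increased Immunologically Active Molecule Activity [PE]			
N0000190201	Vaccines, Attenuated [Chemical/Ingredient]			
N0000190202	BCG Vaccine [Chemical/Ingredient]			
N0000006373	Famotidine [Chemical/Ingredient]			
N0000147595	Mesna			
N0000156948	MESNA 100MG/ML INJ [VA Product]			N0000147595
N0000006244	Fatty Acids, Omega-3 [Chemical/Ingredient]			
N000158434	SILICON DIOXIDE [VA Product]			
N0000175583	Omega-3 Fatty Acid [EPC]			
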