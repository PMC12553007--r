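protein_id	status	drugs	cardiac_indication	cardiac_side_effect
A2MG	druggable	Technetium tc 99m succimer	FALSE	FALSE
ARK72	not_yet_druggable		FALSE	FALSE
APOF	not_yet_druggable		FALSE	FALSE
ATF6B	not_yet_druggable		FALSE	FALSE
AT1B2	drugged	Deslanoside,Digitoxin,Digoxin,Acetyldigitoxin,Istaroxime,Lanatoside c	TRUE	TRUE
C1S	drugged	Human c1-esterase inhibitor,Sutimlimab	FALSE	FALSE
CAH1	drugged	Methocarbamol,Acetazolamide sodium,Dichlorphenamide,Acetazolamide,Methazolamide,Polmacoxib,Ethoxzolamide,Sulthiame	TRUE	TRUE
COMT	drugged	Tolcapone,Entacapone,Opicapone,Nebicapone	FALSE	TRUE
CATD	not_yet_druggable		FALSE	FALSE
CATH	not_yet_druggable		FALSE	FALSE
FER	not_yet_druggable		FALSE	FALSE
IL6RA	drugged	Tocilizumab,Sarilumab,Vobarilizumab,Levilimab,Satralizumab	TRUE	TRUE
NAGK	not_yet_druggable		FALSE	FALSE
PLTP	not_yet_druggable		FALSE	FALSE
SIG14	not_yet_druggable		FALSE	FALSE
SWP70	not_yet_druggable		FALSE	FALSE
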