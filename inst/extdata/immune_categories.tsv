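category	gene
ANTIMICROBIAL	C-type Lectin
ANTIMICROBIAL	Crustin
ANTIMICROBIAL	Carcinin
ANTIMICROBIAL	Anti-LPS factor
CELL ADHESION	Cadherin 23
CELL ADHESION	Integrin alpha
CELL ADHESION	Integrin beta
CELL ADHESION	Integrin beta binding protein
CELL ADHESION	Peroxinectin
CELL ADHESION	Tetraspanin
CELL DEATH	Autophagy protein 9
OXIDATIVE STRESS	Glutathione S-transferase
OXIDATIVE STRESS	Peroxiredoxin
OXIDATIVE STRESS	Thioredoxin
PROTEASES	Aminopeptidase
PROTEASES	Cathepsin A
PROTEASES	Cathepsin B
PROTEASES	Cathepsin L
PROTEASES	Cubilin protease
ProPO CASCADE	Prophenoloxidase
ProPO CASCADE	PO activating factor
PROTEASE INHIBITORS	Serine protease inhibitor
RNAi	Armitage
RNAi	Tudor staphylococcal nuclease
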