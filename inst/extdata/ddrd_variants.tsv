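disease	patient	coordinate_grch38	hgvs_c	hgvs_p	consequence	codon	domain_label	zygosity	dbsnp	hgmd	inmerf	cadd	dann
DDRD	DDRD_P02	21839005	c.9970G>A	p.G3324R	MISSENSE	3324	18th immunoglobulin-like region/Domain IV	Hom	rs1294413650	CM1821690	0.752	0.927	0.989
DDRD	DDRD_P03	21839005	c.9970G>A	p.G3324R	MISSENSE	3324	18th immunoglobulin-like region/Domain IV	Hom	rs1294413650	CM1821690	0.752	0.927	0.989
DDRD	DDRD_P04	21839005	c.9970G>A	p.G3324R	MISSENSE	3324	18th immunoglobulin-like region/Domain IV	C.het	rs1294413650	CM1821690	0.752	0.927	0.989
DDRD	DDRD_P04	21851790	c.7006+1G>A		SPLICING			C.het	rs778653296	CS065567			
DDRD	DDRD_P06	21839005	c.9970G>A	p.G3324R	MISSENSE	3324	18th immunoglobulin-like region/Domain IV	C.het	rs1294413650	CM1821690	0.752	0.927	0.989
DDRD	DDRD_P06	21889996	c.559C>T	p.R187X	NONSENSE	187		C.het	rs1332584154				
DDRD	DDRD_P07	21839005	c.9970G>A	p.G3324R	MISSENSE	3324	18th immunoglobulin-like region/Domain IV	C.het	rs1294413650	CM1821690	0.752	0.927	0.989
DDRD	DDRD_P07	21831213	c.11562+2T>G		SPLICING			C.het		CS151722			
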