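disease	coordinate_grch38	hgvs_c	hgvs_p	consequence	codon	domain_label	dbsnp	hgmd	inmerf	cadd	dann
SJS	21889500	c.574+481C>T		SPLICING			rs916959204	CS065568			
SJS	21887966-21887976	c.665_675del		FRAMESHIFT				CD065741			
SJS	21884528-21887623	c.720_1654del		FRAMESHIFT							
SJS	21885405	c.1125C>G	p.C375W	MISSENSE	375	4th LDL receptor type A/Domain II	rs543805444		0.965	0.382	0.377
SJS	21884877	c.1356-10G>A		SPLICING							
SJS	21884513	c.1654+15G>A		SPLICING			rs886046043	CS1312769			
SJS	21876592	c.2746C>T	p.R916X	NONSENSE	916			CM1312167			
SJS	21876497	c.2826+15G>A		SPLICING							
SJS	21875990	c.3056C>T	p.P1019L	MISSENSE	1019	2nd laminin type B/Domain III	rs62642528	CM065274	0.595	0.319	0.599
SJS	21875668	c.3263T>C	p.L1088P	MISSENSE	1088	2nd laminin type B/Domain III		CM157180	0.335	0.626	0.931
SJS	21872996	c.3888+1G>A		SPLICING							
SJS	21865037	c.4432C>T	p.R1478C	MISSENSE	1478	3rd laminin type B/Domain III	rs1198712778	CM065272	0.515	0.593	0.992
SJS	21864994-21864996	c.4473_4475del		INFRAME				CD065740			
SJS	21864874	c.4595G>A	p.C1532Y	MISSENSE	1532	Interface between 3rd laminin type B and 7th laminin EGF-like/Domain III	rs137853248	CM003145	0.966	0.647	0.749
SJS	21864192	c.4648C>T	p.R1550C	MISSENSE	1550	Interface between 3rd laminin type B and 7th laminin EGF-like/Domain III	rs1317669197	CM065277	0.741	0.705	0.997
SJS	21864100	c.4740G>A		SPLICING				CS003180			
SJS	21864095	c.4740+5G>A		SPLICING			rs886039909	CS1613304			
SJS	21862125	c.4741-10T>G		SPLICING				CS065566			
SJS	21855680	c.5702-5G>A		SPLICING			rs2290498	CS1514375			
SJS	21854720	c.6179delC		FRAMESHIFT				CD065739			
SJS	21851790	c.7006+1G>A		SPLICING			rs778653296	CS065567			
SJS	21850359	c.7294+4A>G		SPLICING				CS021002			
SJS	21847842	c.7874-2A>G		SPLICING			rs931293134	CS065569			
SJS	21847960-21847840	fusion of exons 60 and 61		SPLICING							
SJS	21846108	c.8464G>A		SPLICING			rs748523693	CS021003			
SJS	21846104	c.8464+4A>G		SPLICING			rs1572204991	CS003181			
SJS	21843375	c.8680C>T	p.Q2894X	NONSENSE	2894		rs1004543320	CM065273			
SJS	21842916-21842924	c.8759-3_8764del		INFRAME				CD021017			
SJS	21842892	c.8788G>A	p.E2930K	MISSENSE	2930	Interface between 13th and 14th immunoglobulin-like regions/Domain IV	rs368020528	CM187975	0.286	0.618	0.962
SJS	21842014	c.9181C>T	p.Q3061X	NONSENSE	3061			CM157183			
SJS	21841541	c.9326delA		FRAMESHIFT			rs2098048505	CD065736			
SJS	21839888	c.9643delC		FRAMESHIFT				CD065735			
SJS	21836803	c.10354C>T	p.R3452X	NONSENSE	3452		rs1208167285	CM065275			
SJS	21836802	c.10355G>A	p.R3452Q	MISSENSE	3452	19th immunoglobulin-like region/Domain IV	rs1327754652	CM065276	0.428	0.711	0.989
SJS	21833870	c.10776delT		FRAMESHIFT				CD1514376			
SJS	21833381	c.10982G>A	p.R3661Q	MISSENSE	3661	Interface between 21st immunoglobulin-like region and 1st laminin type G/Domains IV and V			0.489	0.520	0.988
SJS	21833363	c.11000C>T	p.T3667M	MISSENSE	3667	1st laminin type G/Domain V	rs369084217	CM1821688	0.571	0.943	0.968
SJS	21832510	c.11192delG		FRAMESHIFT				CD065738			
SJS	21832495	c.11207G>A	p.R3736Q	MISSENSE	3736	1st laminin type G/Domain V	rs984839674	CM1911787	0.690	0.800	0.997
SJS	21831803	c.11208-7G>A		SPLICING							
SJS	21829582-21829583	c.11792dupC		FRAMESHIFT				CI065834			
SJS	21828878	c.12194delC		FRAMESHIFT				CD065737			
SJS	21824120	c.12899+1G>A		SPLICING							
SJS	21816592-21823699	c.12920del7108		SPLICING							
DDSH	21887995	c.646G>T	p.E216X	NONSENSE	216			CM1310600			
DDSH	21873006-21873009	c.3876_3879del		FRAMESHIFT				CD106077			
DDSH	21872619	c.4029+1G>A		SPLICING			rs779249304	CS188869			
DDSH	21855589	c.5788C>T	p.Q1930X	NONSENSE	1930			CM1310601			
DDSH	21851786	c.7006+5G>A		SPLICING			rs1208832174	CS011045			
DDSH	21839005	c.9970G>A	p.G3324R	MISSENSE	3324	18th immunoglobulin-like region/Domain IV	rs1294413650	CM1821690	0.752	0.927	0.989
DDSH	21833551	c.10894C>T	p.R3632X	NONSENSE	3632		rs762281715	CM1821689			
DDSH	21824603-21824604	c.12666-2_12677dup		FRAMESHIFT				CI2015701			
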