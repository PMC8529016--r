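form	lemma	pos	gender	number	raw_freq	grade
libro	libro	noun	M	SG	5000	
libri	libro	noun	M	PL	3000	
rosa	rosa	noun	F	SG	1200	
rose	rosa	noun	F	PL	800	
fiore	fiore	noun	M	SG	900	
fiori	fiore	noun	M	PL	700	
problema	problema	noun	M	SG	4000	
problemi	problema	noun	M	PL	3500	
uovo	uovo	noun	M	SG	600	
uova	uovo	noun	F	PL	650	
re	re	noun	M	SG	2000	
re	re	noun	M	PL	2000	
sport	sport	noun	M	SG	1500	
sports	sport	noun	M	PL	100	
abitante	abitante	noun	M	SG	800	
abitante	abitante	noun	F	SG	800	
abitanti	abitante	noun	M	PL	1000	
abitanti	abitante	noun	F	PL	1000	
cameriere	cameriere	noun	M	SG	5232	
camerieri	cameriere	noun	M	PL	400	
cameriere	cameriera	noun	F	PL	5232	
cameriera	cameriera	noun	F	SG	300	
portavoce	portavoce	noun	F	SG	450	
portavoce	portavoce	noun	F	PL	450	
portavoce	portavoce	noun	M	SG	450	
portavoce	portavoce	noun	M	PL	450	
bella	bello	adjective	F	SG	2100	positive
belle	bello	adjective	F	PL	1900	positive
bello	bello	adjective	M	SG	2500	positive
belli	bello	adjective	M	PL	1700	positive
grande	grande	adjective	F	SG	3200	positive
grandi	grande	adjective	F	PL	2800	positive
grande	grande	adjective	M	SG	3200	positive
grandi	grande	adjective	M	PL	2800	positive
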