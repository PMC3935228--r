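species	voucher	accession	locality	date	collector
Hermeuptychia sosybius	13386A07	KJ025561	USA: Georgia: Chatham Co., Savannah	28-Jul-1958	G. B. Small
Hermeuptychia intricata	NVG-1560	KJ025595	USA: Texas: Fort Bend Co., Brazos Bend State Park	17-Aug-2013	N. V. Grishin
Hermeuptychia hermybius	NVG-1603	KJ025569	USA: Texas: Cameron Co., E of Brownsville	17-Mar-2003	N. V. Grishin
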