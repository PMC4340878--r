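locus_tag	gene_name	function	category	note
SCO1552		rRNA methylase	2.2.11 RNA synthesis, modification, DNA transcription
SCO1553	cysG	Putative uroporphyrin-III methyltransferase	3.2.6 Heme, porphyrin	*
SCO1707		Putative ABC sugar transporter, ATP-binding subunit	1.5.0 Transport/binding proteins	*
SCO1776	pyrG	Putative CTP synthetase	3.3.11 Nucleotide interconversions	*, I
SCO2103	metF	5,10-methylenetetrahydrofolate reductase	3.1.14 Methionine	*
SCO2910	cysM	Cysteine synthase	3.1.6 Cysteine
SCO2911		Hypothetical protein	0.0.2 Conserved in organism other than Escherichia coli
SCO2912		Hypothetical protein	0.0.0 Unknown function, no known homologs	*
SCO2999	gdhB	Glutamate dehydrogenase	0.0.2 Conserved in organism other than Escherichia coli	*, I
SCO3345	ilvD	Dihydroxy acid dehydratase	3.1.21 Valine	*
SCO4164	cysA	Putative thiosulfate sulfurtransferase	3.3.19 Sulfur metabolism	*
SCO4165		Hypothetical protein	0.0.2 Conserved in organism other than Escherichia coli
SCO4193		Putative ATP/GTP-binding membrane protein	4.1.6 Gram +ve membrane	*, I
SCO5178	moeB	Putative sulfurylase	3.2.14 Thiamine	*
SCO5277		Magnesium chelatase	7.0.0 Not classified (included putative assignments)	*, I
SCO5395		Putative ABC transporter ATP-binding subunit	1.5.0 Transport/binding proteins	*
SCO5413		Possible MarR-transcriptional regulator	6.3.7 MarR	*
SCO5512	ilvB	Acetolactate synthase	3.4.3 Carbon compounds	*
SCO5513	ilvN	Acetolactate synthase 3 regulatory subunit	3.1.21 Valine
SCO5514	ilvC	Acetolactate synthase small subunit	3.1.21 Valine
SCO5522	leuB	3-isopropylmalate dehydrogenase	3.1.12 Leucine	*
SCO5523	ilvE	Branched-chain amino acid aminotransferase	3.1.21 Valine
SCO5552	ndgR	Putative regulator	6.5.0 Others	*, D
SCO5553	leuC	Isopropylmalate isomerase large subunit	3.1.12 Leucine	*, D
SCO5554	leuD	Isopropylmalate isomerase small subunit	3.1.12 Leucine
SCO5562	thiL	Thiamin monophosphate kinase	3.2.14 Thiamine	*
SCO5563	thiD	Phosphomethylpyrimidine kinase	3.3.14 Thiamine
SCO6097	cysN	Sulfate adenylyltransferase subunit 1	3.3.19 Sulfur metabolism
SCO6098	cysD	Sulfate adenylyltransferase subunit 2	3.3.19 Sulfur metabolism
SCO6099	cysC	Adenylylsulphate kinase	3.3.19 Sulfur metabolism
SCO6100	cysH	Phosphoadenosine phosphosulfate reductase	3.3.19 Sulfur metabolism
SCO6101		Hypothetical protein	0.0.0 Unknown function, no known homologs
SCO6102	cysI	Putative nitrite/sulfite reductase	3.5.2 Anaerobic respiration	*
SCO6510		Conserved hypothetical protein	0.0.2 Conserved in organism other than Escherichia coli	*
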