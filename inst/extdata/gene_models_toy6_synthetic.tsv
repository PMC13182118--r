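gene	chrom	start	end	strand	exons	cds_start	cds_end	signal_peptide_len	cds_sequence	flank	reference_variant_name
CSN1S1	6	85411118	85429268	+	85412118-85412227;85412428-85412487;85412788-85412887	85412168	85412847	15	ATGGCTGATAAAGCTTCTGGATTTCTGATTGAAGTTTACTGGAGAACACAAAGCCGTATGCATGCTGATAAAGCTTCTGGATTTCTGATTGAAGTTTACTGGAGAACAAGCAGCCGTATGCATGCTGATAAACCTCATGGATTTCTGATTGAAGTTTACTGGGGAACACAAAGCCGTATG	2000	B
CSN2	6	85449164	85457744	-	85455840-85455984;85456285-85456389;85456590-85456744	85455880	85456694	15	ATGGCTGATAAAGCTTCTGGATTTCTGATTGAAGTTTACTGGAGAACACAAAGCCGTATGCATGCTGATAAAGCTTCTGGATTTCTGATTGAAGTTTACTGGAGAACACAAAGCCGTATGCATGCTGATAAACCTTCTGGATTTCTGATTAGCGTTTACTGGAGAACACAAAGCCGTATGCATGCTGATAAACCTTCTGGATTTCTGATTGAAGTTTACTGGAGAACACAAAGCCGTATGCATCATGATAAACCTTCTGGATTTCTGATTGAAGTTTACTGGGGAACACAAAGCCGTATGCATGCTGATAAACCT	2000	B
CSN1S2	6	85529905	85548556	+	85530905-85531014;85531215-85531274;85531575-85531674	85530955	85531634	15	ATGGCTGATAAAGCTTCTGGATTTCTGATTGAAGTTTACTGGAGAACACAAAGCCGTATGCATGCTGATAAAGCTTCTGGATTTCTGATTGAAGTTTACTGGAGAACAAGCAGCCGTATGCATGCTGATAAACCTCATGGATTTCTGATTGAAGTTTACTGGGGAACACAAAGCCGTATG	2000	A
CSN3	6	85645854	85658926	+	85646854-85647093;85647294-85647483;85647784-85648013	85646904	85647973	21	ATGGCTGATAAAGCTTCTGGATTTCTGATTGAAGTTTACTGGAGAACACAAAGCCGTATGCATGCTGATAAACCTTCTGGATTTCTGATTGCTGTTTACTGGAGAACACAAAGCCGTATGCATGCTGATAAACCTTCTGGATTTCTGATTGAAGTTTACTGGAGAACACAAAGCCGTATGCATGCTGATAAACCTTCTGGATTTCTGATTAGCGTTTACTGGAGAACACAAAGCCGTATGCATGCTGATAAACCTTCTGGATTTCTGATTGAAGTTTACTGGAGAACACAAAGCCGTATGCATGCTGATAAACCTTCTGGATTTCTGATTGAAGTTTACTGGAGAACACAAAGCCGTATGCATGCTGATAAACCTTCTGGATTTCTGATTGAAGTTTACTGGAGAACACAAAGCCGTATGCATGCTGATAAACCTTCTGGATTTCTGATTGAAGTTTACTGGAGAACACATAGCCGTATGCATGCTGATAAACCTTCTGGATTTCTGGGAGAAGTTTACTGGAGAACACAAAGCCGTATGCATGCTGATAAACCTTCTGGATTTCTGATT	2000	B
LALBA	5	31183432	31186209	+	31184432-31184521;31184722-31184761;31185062-31185141	31184482	31185101	19	ATGGCTGATAAAGCTTCTGGATTTCTGATTGAAGTTTACTGGAGAACACAAAGCCGTATGCATGCTGATAAACCTTCTAGCTTTGCTATTGAAGTTCATTGGAGAACACAAGGACGTATG	2000	B
PAEP	11	103255824	103260873	+	103256824-103256933;103257134-103257193;103257494-103257593	103256874	103257553	16	ATGGCTGATAAAGCTTCTGGATTTCTGATTGAAGTTTACTGGAGAACACAAAGCCGTATGCATGCTGATAAACCTGCTGGATTTCTGATTGAAGTTTACTGGAGAAGCCAAAGCCGTATGCATGCTGATAAACCTCATGGATTTCTGATTGAAGTTTACTGGAGAGGACAAAGCCGTATG	2000	B
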