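##fileformat=VCFv4.2
##source=lactovar-fixture
##INFO=<ID=MQ,Number=1,Type=Float,Description="Mapping quality">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2	S3	S4
6	85646000	.	A	G	50.0	PASS	MQ=60.0	GT:AD:DP	0/1:5,5:10	0/1:5,5:10	0/0:10,0:10	0/0:10,0:10
6	85646100	.	C	T	19.9	PASS	MQ=60.0	GT:AD:DP	0/1:5,5:10	0/1:5,5:10	0/0:10,0:10	0/0:10,0:10
6	85646200	.	G	A	50.0	PASS	MQ=60.0	GT:AD:DP	0/1:6,6:12	0/0:10,0:10	0/0:10,0:10	0/0:10,0:10
6	85646300	.	T	C	50.0	PASS	MQ=60.0	GT:AD:DP	1/1:0,12:12	1/1:0,11:11	0/0:10,0:10	0/0:10,0:10
6	85646400	.	A	C	50.0	PASS	MQ=60.0	GT:AD:DP	0/1:4,4:8	0/1:5,5:10	0/1:6,6:12	0/0:10,0:10
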