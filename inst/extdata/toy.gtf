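chr1	longfuse	gene	101	1000	.	+	.	gene_id "GA"; gene_name "ALPHA";
chr1	longfuse	transcript	101	1000	.	+	.	gene_id "GA"; transcript_id "GA.t1"; gene_name "ALPHA";
chr1	longfuse	exon	101	200	.	+	.	gene_id "GA"; transcript_id "GA.t1"; gene_name "ALPHA";
chr1	longfuse	exon	401	500	.	+	.	gene_id "GA"; transcript_id "GA.t1"; gene_name "ALPHA";
chr1	longfuse	exon	901	1000	.	+	.	gene_id "GA"; transcript_id "GA.t1"; gene_name "ALPHA";
chr1	longfuse	gene	2001	3000	.	-	.	gene_id "GB"; gene_name "BETA";
chr1	longfuse	transcript	2001	3000	.	-	.	gene_id "GB"; transcript_id "GB.t1"; gene_name "BETA";
chr1	longfuse	exon	2001	2100	.	-	.	gene_id "GB"; transcript_id "GB.t1"; gene_name "BETA";
chr1	longfuse	exon	2901	3000	.	-	.	gene_id "GB"; transcript_id "GB.t1"; gene_name "BETA";
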