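chr1	primatesplice	exon	201	392	.	+	.	gene_id "g001"; transcript_id "g001.t1";
chr1	primatesplice	exon	640	735	.	+	.	gene_id "g001"; transcript_id "g001.t1";
chr1	primatesplice	exon	945	1127	.	+	.	gene_id "g001"; transcript_id "g001.t1";
chr1	primatesplice	exon	1372	1485	.	+	.	gene_id "g001"; transcript_id "g001.t1";
chr1	primatesplice	exon	1694	1876	.	+	.	gene_id "g001"; transcript_id "g001.t1";
chr1	primatesplice	exon	2040	2231	.	+	.	gene_id "g001"; transcript_id "g001.t1";
chr1	primatesplice	exon	201	392	.	+	.	gene_id "g001"; transcript_id "g001.t2";
chr1	primatesplice	exon	945	1127	.	+	.	gene_id "g001"; transcript_id "g001.t2";
chr1	primatesplice	exon	1372	1485	.	+	.	gene_id "g001"; transcript_id "g001.t2";
chr1	primatesplice	exon	1694	1876	.	+	.	gene_id "g001"; transcript_id "g001.t2";
chr1	primatesplice	exon	2040	2231	.	+	.	gene_id "g001"; transcript_id "g001.t2";
chr1	primatesplice	exon	201	392	.	+	.	gene_id "g001"; transcript_id "g001.t3";
chr1	primatesplice	exon	640	735	.	+	.	gene_id "g001"; transcript_id "g001.t3";
chr1	primatesplice	exon	1372	1485	.	+	.	gene_id "g001"; transcript_id "g001.t3";
chr1	primatesplice	exon	1694	1876	.	+	.	gene_id "g001"; transcript_id "g001.t3";
chr1	primatesplice	exon	2040	2231	.	+	.	gene_id "g001"; transcript_id "g001.t3";
chr1	primatesplice	exon	201	392	.	+	.	gene_id "g001"; transcript_id "g001.tg";
chr1	primatesplice	exon	640	699	.	+	.	gene_id "g001"; transcript_id "g001.tg";
chr1	primatesplice	exon	945	1127	.	+	.	gene_id "g001"; transcript_id "g001.tg";
chr1	primatesplice	exon	1372	1485	.	+	.	gene_id "g001"; transcript_id "g001.tg";
chr1	primatesplice	exon	1694	1876	.	+	.	gene_id "g001"; transcript_id "g001.tg";
chr1	primatesplice	exon	2040	2231	.	+	.	gene_id "g001"; transcript_id "g001.tg";
chr2	primatesplice	exon	201	389	.	+	.	gene_id "g002"; transcript_id "g002.t1";
chr2	primatesplice	exon	654	839	.	+	.	gene_id "g002"; transcript_id "g002.t1";
chr2	primatesplice	exon	998	1177	.	+	.	gene_id "g002"; transcript_id "g002.t1";
chr2	primatesplice	exon	1390	1548	.	+	.	gene_id "g002"; transcript_id "g002.t1";
chr2	primatesplice	exon	1743	1856	.	+	.	gene_id "g002"; transcript_id "g002.t1";
chr2	primatesplice	exon	2092	2211	.	+	.	gene_id "g002"; transcript_id "g002.t1";
chr2	primatesplice	exon	201	389	.	+	.	gene_id "g002"; transcript_id "g002.t2";
chr2	primatesplice	exon	998	1177	.	+	.	gene_id "g002"; transcript_id "g002.t2";
chr2	primatesplice	exon	1390	1548	.	+	.	gene_id "g002"; transcript_id "g002.t2";
chr2	primatesplice	exon	1743	1856	.	+	.	gene_id "g002"; transcript_id "g002.t2";
chr2	primatesplice	exon	2092	2211	.	+	.	gene_id "g002"; transcript_id "g002.t2";
chr2	primatesplice	exon	201	389	.	+	.	gene_id "g002"; transcript_id "g002.t3";
chr2	primatesplice	exon	654	839	.	+	.	gene_id "g002"; transcript_id "g002.t3";
chr2	primatesplice	exon	1390	1548	.	+	.	gene_id "g002"; transcript_id "g002.t3";
chr2	primatesplice	exon	1743	1856	.	+	.	gene_id "g002"; transcript_id "g002.t3";
chr2	primatesplice	exon	2092	2211	.	+	.	gene_id "g002"; transcript_id "g002.t3";
chr3	primatesplice	exon	201	371	.	+	.	gene_id "g003"; transcript_id "g003.t1";
chr3	primatesplice	exon	666	815	.	+	.	gene_id "g003"; transcript_id "g003.t1";
chr3	primatesplice	exon	1017	1133	.	+	.	gene_id "g003"; transcript_id "g003.t1";
chr3	primatesplice	exon	1294	1422	.	+	.	gene_id "g003"; transcript_id "g003.t1";
chr3	primatesplice	exon	1584	1745	.	+	.	gene_id "g003"; transcript_id "g003.t1";
chr3	primatesplice	exon	201	371	.	+	.	gene_id "g003"; transcript_id "g003.t2";
chr3	primatesplice	exon	1017	1133	.	+	.	gene_id "g003"; transcript_id "g003.t2";
chr3	primatesplice	exon	1294	1422	.	+	.	gene_id "g003"; transcript_id "g003.t2";
chr3	primatesplice	exon	1584	1745	.	+	.	gene_id "g003"; transcript_id "g003.t2";
chr3	primatesplice	exon	201	371	.	+	.	gene_id "g003"; transcript_id "g003.t3";
chr3	primatesplice	exon	666	815	.	+	.	gene_id "g003"; transcript_id "g003.t3";
chr3	primatesplice	exon	1294	1422	.	+	.	gene_id "g003"; transcript_id "g003.t3";
chr3	primatesplice	exon	1584	1745	.	+	.	gene_id "g003"; transcript_id "g003.t3";
chr4	primatesplice	exon	201	356	.	+	.	gene_id "g004"; transcript_id "g004.t1";
chr4	primatesplice	exon	520	678	.	+	.	gene_id "g004"; transcript_id "g004.t1";
chr4	primatesplice	exon	875	1030	.	+	.	gene_id "g004"; transcript_id "g004.t1";
chr4	primatesplice	exon	1277	1462	.	+	.	gene_id "g004"; transcript_id "g004.t1";
chr4	primatesplice	exon	1688	1852	.	+	.	gene_id "g004"; transcript_id "g004.t1";
chr4	primatesplice	exon	2049	2204	.	+	.	gene_id "g004"; transcript_id "g004.t1";
chr4	primatesplice	exon	201	356	.	+	.	gene_id "g004"; transcript_id "g004.t2";
chr4	primatesplice	exon	875	1030	.	+	.	gene_id "g004"; transcript_id "g004.t2";
chr4	primatesplice	exon	1277	1462	.	+	.	gene_id "g004"; transcript_id "g004.t2";
chr4	primatesplice	exon	1688	1852	.	+	.	gene_id "g004"; transcript_id "g004.t2";
chr4	primatesplice	exon	2049	2204	.	+	.	gene_id "g004"; transcript_id "g004.t2";
chr4	primatesplice	exon	201	356	.	+	.	gene_id "g004"; transcript_id "g004.t3";
chr4	primatesplice	exon	520	678	.	+	.	gene_id "g004"; transcript_id "g004.t3";
chr4	primatesplice	exon	1277	1462	.	+	.	gene_id "g004"; transcript_id "g004.t3";
chr4	primatesplice	exon	1688	1852	.	+	.	gene_id "g004"; transcript_id "g004.t3";
chr4	primatesplice	exon	2049	2204	.	+	.	gene_id "g004"; transcript_id "g004.t3";
chr5	primatesplice	exon	201	389	.	+	.	gene_id "g005"; transcript_id "g005.t1";
chr5	primatesplice	exon	659	769	.	+	.	gene_id "g005"; transcript_id "g005.t1";
chr5	primatesplice	exon	925	1080	.	+	.	gene_id "g005"; transcript_id "g005.t1";
chr5	primatesplice	exon	1373	1483	.	+	.	gene_id "g005"; transcript_id "g005.t1";
chr5	primatesplice	exon	1658	1852	.	+	.	gene_id "g005"; transcript_id "g005.t1";
chr5	primatesplice	exon	201	389	.	+	.	gene_id "g005"; transcript_id "g005.t2";
chr5	primatesplice	exon	925	1080	.	+	.	gene_id "g005"; transcript_id "g005.t2";
chr5	primatesplice	exon	1373	1483	.	+	.	gene_id "g005"; transcript_id "g005.t2";
chr5	primatesplice	exon	1658	1852	.	+	.	gene_id "g005"; transcript_id "g005.t2";
chr5	primatesplice	exon	201	389	.	+	.	gene_id "g005"; transcript_id "g005.t3";
chr5	primatesplice	exon	659	769	.	+	.	gene_id "g005"; transcript_id "g005.t3";
chr5	primatesplice	exon	1373	1483	.	+	.	gene_id "g005"; transcript_id "g005.t3";
chr5	primatesplice	exon	1658	1852	.	+	.	gene_id "g005"; transcript_id "g005.t3";
chr6	primatesplice	exon	201	389	.	+	.	gene_id "g006"; transcript_id "g006.t1";
chr6	primatesplice	exon	641	793	.	+	.	gene_id "g006"; transcript_id "g006.t1";
chr6	primatesplice	exon	978	1124	.	+	.	gene_id "g006"; transcript_id "g006.t1";
chr6	primatesplice	exon	1413	1568	.	+	.	gene_id "g006"; transcript_id "g006.t1";
chr6	primatesplice	exon	1765	1965	.	+	.	gene_id "g006"; transcript_id "g006.t1";
chr6	primatesplice	exon	201	389	.	+	.	gene_id "g006"; transcript_id "g006.t2";
chr6	primatesplice	exon	978	1124	.	+	.	gene_id "g006"; transcript_id "g006.t2";
chr6	primatesplice	exon	1413	1568	.	+	.	gene_id "g006"; transcript_id "g006.t2";
chr6	primatesplice	exon	1765	1965	.	+	.	gene_id "g006"; transcript_id "g006.t2";
chr6	primatesplice	exon	201	389	.	+	.	gene_id "g006"; transcript_id "g006.t3";
chr6	primatesplice	exon	641	793	.	+	.	gene_id "g006"; transcript_id "g006.t3";
chr6	primatesplice	exon	1413	1568	.	+	.	gene_id "g006"; transcript_id "g006.t3";
chr6	primatesplice	exon	1765	1965	.	+	.	gene_id "g006"; transcript_id "g006.t3";
chr6	primatesplice	exon	201	389	.	+	.	gene_id "g006"; transcript_id "g006.tn";
chr6	primatesplice	exon	641	685	.	+	.	gene_id "g006"; transcript_id "g006.tn";
chr6	primatesplice	exon	978	1124	.	+	.	gene_id "g006"; transcript_id "g006.tn";
chr6	primatesplice	exon	1413	1568	.	+	.	gene_id "g006"; transcript_id "g006.tn";
chr6	primatesplice	exon	1765	1965	.	+	.	gene_id "g006"; transcript_id "g006.tn";
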