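# Editable alias map: raw gene names (GenBank qualifiers, published tables)
# to canonical symbols. Matching is case-insensitive on alphanumerics only,
# so "tRNA-Met", "trnM" and "TRNAMET" all hit the same row.
alias	canonical
COX1	COI
COXI	COI
CO1	COI
COX2	COII
COXII	COII
CO2	COII
COX3	COIII
COXIII	COIII
CO3	COIII
COB	CytB
CYTB	CytB
CYB	CytB
NAD1	ND1
NAD2	ND2
NAD3	ND3
NAD4	ND4
NAD4L	ND4L
NAD5	ND5
NAD6	ND6
NADH1	ND1
NADH2	ND2
NADH3	ND3
NADH4	ND4
NADH4L	ND4L
NADH5	ND5
NADH6	ND6
ATPASE6	ATP6
ATPASE8	ATP8
ATP SYNTHASE F0 SUBUNIT 6	ATP6
ATP SYNTHASE F0 SUBUNIT 8	ATP8
LRRNA	rrnL
SRRNA	rrnS
RRNL	rrnL
RRNS	rrnS
RRN16	rrnL
RRN12	rrnS
16S	rrnL
12S	rrnS
16S RIBOSOMAL RNA	rrnL
12S RIBOSOMAL RNA	rrnS
RRNAL	rrnL
RRNAS	rrnS
DLOOP	control_region
CR	control_region
AT RICH REGION	control_region
A+T RICH REGION	control_region
CONTROL REGION	control_region
TRNAALA	trnA
TRNAARG	trnR
TRNAASN	trnN
TRNASN	trnN
TRNAASP	trnD
TRNACYS	trnC
TRNAGLN	trnQ
TRNAGLU	trnE
TRNAGLY	trnG
TRNAHIS	trnH
TRNAILE	trnI
TRNALEUCUN	trnL1
TRNALEUUUR	trnL2
TRNALEUUUN	trnL2
TRNAL1	trnL1
TRNAL2	trnL2
TRNALYS	trnK
TRNAMET	trnM
TRNAPHE	trnF
TRNAPRO	trnP
TRNASERAGN	trnS1
TRNASERUCN	trnS2
TRNAS1	trnS1
TRNAS2	trnS2
TRNATHR	trnT
TRNATRP	trnW
TRNATYR	trnY
TRNAVAL	trnV
TRNA	trnA
TRNR	trnR
TRNN	trnN
TRND	trnD
TRNC	trnC
TRNQ	trnQ
TRNE	trnE
TRNG	trnG
TRNH	trnH
TRNI	trnI
TRNL1	trnL1
TRNL2	trnL2
TRNLCUN	trnL1
TRNLUUR	trnL2
TRNK	trnK
TRNM	trnM
TRNF	trnF
TRNP	trnP
TRNS1	trnS1
TRNS2	trnS2
TRNSAGN	trnS1
TRNSUCN	trnS2
TRNT	trnT
TRNW	trnW
TRNY	trnY
TRNV	trnV
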