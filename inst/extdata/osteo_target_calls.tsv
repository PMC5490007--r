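sample	gene	call	significant
PD13486a	TERT	-	FALSE
PD13486a	RICTOR	+3	TRUE
PD7190a	TERT	+1	FALSE
PD7190a	RICTOR	+6	TRUE
PD9962a	TERT	+5	TRUE
PD9962a	RICTOR	+2	TRUE
PD13490a	TERT	+4	TRUE
PD13490a	RICTOR	+7	TRUE
PD13490a	TP53	LOH	NA
PD13490a	COPS3	+13	TRUE
PD13490a	NF1	BP	NA
PD13478a	CCND2	+1	FALSE
PD13478a	MDM2	+20	TRUE
PD13478a	CDK4	+22	TRUE
PD13495a	CCND2	+1	FALSE
PD13495a	MDM2	+5	TRUE
PD13495a	CDK4	-	FALSE
PD7401a	CCND2	+6	TRUE
PD7401a	MDM2	+10	TRUE
PD7401a	CDK4	+8	TRUE
PD7508a	CCND2	+2	TRUE
PD7508a	MDM2	+17	TRUE
PD7508a	CDK4	+23	TRUE
PD13492a	CCND2	+1	FALSE
PD13492a	MDM2	-	FALSE
PD13492a	CDK4	+15	TRUE
PD13492a	TP53	LOH+BP	NA
PD13492a	COPS3	+16	TRUE
PD13492a	NF1	-	NA
PD13476a	TP53	LOH+BP	NA
PD13476a	COPS3	+16	TRUE
PD13476a	NF1	LOH	NA
PD7513a	TP53	LOH+BP	NA
PD7513a	COPS3	+25	TRUE
PD7513a	NF1	LOH	NA
PD9056a	TP53	LOH+BP	NA
PD9056a	COPS3	+26	TRUE
PD9056a	NF1	-	NA
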