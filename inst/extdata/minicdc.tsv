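!!SBtab SBtabVersion='1.0' Document='rxncycle' TableType='ComponentList' TableName='ComponentList'
!Name	!Kind	!Protein
Cdc28	protein	
Cln3	protein	
SBF	protein	
Cln2	protein	
Clb5	protein	
Clb2	protein	
Sic1	protein	
Far1	protein	
Net1	protein	
Cdc14	protein	
Chs2	protein	
Bys1	protein	
Fus3	enzymatic-activity	
PPT1	enzymatic-activity	
BysK	enzymatic-activity	
CLN3g	gene	Cln3
CLN2g	gene	Cln2
CLB5g	gene	Clb5
CLB2g	gene	Clb2
SIC1g	gene	Sic1
CLN3m	mRNA	Cln3
CLN2m	mRNA	Cln2
CLB5m	mRNA	Clb5
CLB2m	mRNA	Clb2
SIC1m	mRNA	Sic1

!!SBtab SBtabVersion='1.0' Document='rxncycle' TableType='ReactionTypeList' TableName='ReactionTypeList'
!ReactionType	!Category	!Modification	!DelayedByDefault
ppi+	bond_formation		
ppi-	bond_dissociation		
P+	mod_addition	P	
P-	mod_removal	P	
Ub+	mod_addition	Ub	
Ub-	mod_removal	Ub	
trsc	transcription		yes
trsl	translation		
syn	synthesis		
deg	degradation		
mt	macro_transition		
msyn	macro_synthesis		

!!SBtab SBtabVersion='1.0' Document='rxncycle' TableType='ReactionList' TableName='ReactionList'
!UID:Reaction	!ComponentA:Name	!ComponentA:Domain	!ComponentA:Residue	!Reaction	!ComponentB:Name	!ComponentB:Domain	!ComponentB:Residue	!Timescale	!NoTurnover
Cdc28_syn	Cdc28			syn					yes
SBF_syn	SBF			syn					yes
Far1_syn	Far1			syn					yes
CLN3g_trsc	CLN3g			trsc					
CLN3m_trsl	CLN3m			trsl					
CLN3m_deg	CLN3m			deg	CLN3m				
Cln3_deg	Cln3			deg	Cln3				
Cln3_P+_SBF_[r1]	Cln3			P+	SBF		r1		
PPT1_P-_SBF_[r1]	PPT1			P-	SBF		r1		
CLN2g_trsc	CLN2g			trsc					
CLN2m_trsl	CLN2m			trsl					
CLN2m_deg	CLN2m			deg	CLN2m				
Cln2_deg	Cln2			deg	Cln2				
CLB5g_trsc	CLB5g			trsc					
CLB5m_trsl	CLB5m			trsl					
CLB5m_deg	CLB5m			deg	CLB5m				
Clb5_deg	Clb5			deg	Clb5				
Cdc28_[cyclin]_ppi+_Cln2_[cdc28]	Cdc28	cyclin		ppi+	Cln2	cdc28			
Cdc28_[cyclin]_ppi+_Clb5_[cdc28]	Cdc28	cyclin		ppi+	Clb5	cdc28			
Cdc28_P+_Sic1_[t2]	Cdc28			P+	Sic1		t2		
SIC1g_trsc	SIC1g			trsc					
SIC1m_trsl	SIC1m			trsl					
SIC1m_deg	SIC1m			deg	SIC1m				
Sic1_deg	Sic1			deg	Sic1				
Fus3_P+_Far1_[s1]	Fus3			P+	Far1		s1		
PPT1_P-_Far1_[s1]	PPT1			P-	Far1		s1		
CLB2g_trsc	CLB2g			trsc					
CLB2m_trsl	CLB2m			trsl					
CLB2m_deg	CLB2m			deg	CLB2m				
Clb2_deg	Clb2			deg	Clb2				
Cdc28_[cyclin]_ppi+_Clb2_[cdc28]	Cdc28	cyclin		ppi+	Clb2	cdc28			
Net1_[cdc14]_ppi+_Cdc14_[net1]	Net1	cdc14		ppi+	Cdc14	net1			
Net1_[cdc14]_ppi-_Cdc14_[net1]	Net1	cdc14		ppi-	Cdc14	net1			
Chs2_syn	Chs2			syn					yes
Cdc28_P+_Chs2_[c1]	Cdc28			P+	Chs2		c1		
PPT1_P-_Chs2_[c1]	PPT1			P-	Chs2		c1		
Bys1_syn	Bys1			syn					yes
BysK_P+_Bys1_[b1]	BysK			P+	Bys1		b1		
PPT1_P-_Bys1_[b1]	PPT1			P-	Bys1		b1		
[DNAlicensed]_msyn	[DNAlicensed]			msyn	[DNAlicensed]				
[DNAlicensed]_mt_[DNAreplicating]	[DNAlicensed]			mt	[DNAreplicating]				
[DNAreplicating]_mt_[DNAreplicated]	[DNAreplicating]			mt	[DNAreplicated]			slow	
[DNAreplicated]_mt_[DNAsegregated]	[DNAreplicated]			mt	[DNAsegregated]				
[DNAsegregated]_mt_[DNAlicensed]	[DNAsegregated]			mt	[DNAlicensed]				
[SPBsatellite]_msyn	[SPBsatellite]			msyn	[SPBsatellite]				
[SPBsatellite]_mt_[SPBduplicated]	[SPBsatellite]			mt	[SPBduplicated]				
[SPBduplicated]_mt_[SPBseparated]	[SPBduplicated]			mt	[SPBseparated]				
[SPBseparated]_mt_[SPBsatellite]	[SPBseparated]			mt	[SPBsatellite]				
[BUDnone]_msyn	[BUDnone]			msyn	[BUDnone]				
[BUDnone]_mt_[BUDsmall]	[BUDnone]			mt	[BUDsmall]				
[BUDsmall]_mt_[BUDlarge]	[BUDsmall]			mt	[BUDlarge]			slow	
[BUDlarge]_mt_[BUDdivided]	[BUDlarge]			mt	[BUDdivided]				
[BUDdivided]_mt_[BUDnone]	[BUDdivided]			mt	[BUDnone]				

!!SBtab SBtabVersion='1.0' Document='rxncycle' TableType='ContingencyList' TableName='ContingencyList'
!UID:Contingency	!Target	!Contingency	!Modifier
C001	CLN3g_trsc	!	[Nutrients]
C002	CLN2g_trsc	!	SBF_[r1]-P
C003	CLN2g_trsc	x	Far1_[s1]-P
C004	CLB5g_trsc	!	SBF_[r1]-P
C005	Cdc28_P+_Sic1_[t2]	!	Cdc28_[cyclin]--Cln2_[cdc28]
C006	Sic1_deg	!	Sic1_[t2]-P
C007	SIC1g_trsc	x	Cdc28_[cyclin]--Cln2_[cdc28]
C008	Fus3_P+_Far1_[s1]	!	[Pheromone]
C009	Cdc28_[cyclin]_ppi+_Cln2_[cdc28]	k+	SBF_[r1]-P
C010	<G2M>	AND	[DNAreplicated]
C011	<G2M>	AND	[BUDlarge]
C012	CLB2g_trsc	!	<G2M>
C013	Net1_[cdc14]_ppi-_Cdc14_[net1]	!	Cdc28_[cyclin]--Clb2_[cdc28]
C014	[START]	!	Cdc28_[cyclin]--Cln2_[cdc28]
C015	[START]	!	Cdc28_[cyclin]--Clb5_[cdc28]
C016	[START]	x	Sic1_[t2]-0
C017	[MITOSIS]	!	Cdc28_[cyclin]--Clb2_[cdc28]
C018	[RESET]	!	Cdc14_[net1]--0
C019	[RESET]	!	[DNAsegregated]
C020	[RESET]	!	[SPBseparated]
C021	[DNAlicensed]_msyn	x	[DNAreplicating]
C022	[DNAlicensed]_msyn	x	[DNAreplicated]
C023	[DNAlicensed]_msyn	x	[DNAsegregated]
C024	[DNAlicensed]_mt_[DNAreplicating]	!	[DNAlicensed]
C025	[DNAlicensed]_mt_[DNAreplicating]	!	[START]
C026	[DNAlicensed]_mt_[DNAreplicating]	!	[Nutrients]
C027	[DNAreplicating]_mt_[DNAreplicated]	!	[DNAreplicating]
C028	[DNAreplicating]_mt_[DNAreplicated]	!	[Histones]
C029	[DNAreplicating]_mt_[DNAreplicated]	x	[HU]
C030	[DNAreplicated]_mt_[DNAsegregated]	!	[DNAreplicated]
C031	[DNAreplicated]_mt_[DNAsegregated]	!	[MITOSIS]
C032	[DNAsegregated]_mt_[DNAlicensed]	!	[DNAsegregated]
C033	[DNAsegregated]_mt_[DNAlicensed]	!	[RESET]
C034	[SPBsatellite]_msyn	x	[SPBduplicated]
C035	[SPBsatellite]_msyn	x	[SPBseparated]
C036	[SPBsatellite]_mt_[SPBduplicated]	!	[SPBsatellite]
C037	[SPBsatellite]_mt_[SPBduplicated]	!	[START]
C038	[SPBsatellite]_mt_[SPBduplicated]	!	[Nutrients]
C039	[SPBduplicated]_mt_[SPBseparated]	!	[SPBduplicated]
C040	[SPBduplicated]_mt_[SPBseparated]	!	[MITOSIS]
C041	[SPBseparated]_mt_[SPBsatellite]	!	[SPBseparated]
C042	[SPBseparated]_mt_[SPBsatellite]	!	[RESET]
C043	[BUDnone]_msyn	x	[BUDsmall]
C044	[BUDnone]_msyn	x	[BUDlarge]
C045	[BUDnone]_msyn	x	[BUDdivided]
C046	[BUDnone]_mt_[BUDsmall]	!	[BUDnone]
C047	[BUDnone]_mt_[BUDsmall]	!	[START]
C048	[BUDnone]_mt_[BUDsmall]	!	[Nutrients]
C049	[BUDsmall]_mt_[BUDlarge]	!	[BUDsmall]
C050	[BUDlarge]_mt_[BUDdivided]	!	[BUDlarge]
C051	[BUDlarge]_mt_[BUDdivided]	!	[RESET]
C052	[BUDlarge]_mt_[BUDdivided]	!	Chs2_[c1]-0
C053	[BUDdivided]_mt_[BUDnone]	!	[BUDdivided]
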