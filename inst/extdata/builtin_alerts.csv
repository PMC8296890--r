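alert_id,smarts,description,family,source
nb_any,[#7]c1ccccc1,benzene ring with nitrogen-containing substituent,N-benzene,curated reactive-metabolite alert set
nb_two_nh,[NX3;H2]c1ccccc1,benzene ring with nitrogen-containing substituent (two N-H bond),N-benzene,curated reactive-metabolite alert set
nb_one_nh,[NX3;H1]c1ccccc1,benzene ring with nitrogen-containing substituent (one N-H bond),N-benzene,curated reactive-metabolite alert set
nb_no_nh,[#7;H0]c1ccccc1,benzene ring with nitrogen-containing substituent (no N-H bond),N-benzene,curated reactive-metabolite alert set
alkene,[CX3]=[CX3],alkenes,,curated reactive-metabolite alert set
halomethylbenzene,"[F,Cl,Br,I][CX4]c1ccccc1",methylbenzene with halogenation at the methyl group,,curated reactive-metabolite alert set
phenol,[OX2H]c1ccccc1,benzene ring with hydroxyl group,,curated reactive-metabolite alert set
halogenated_carbon,"[CX4][F,Cl,Br,I]",halogenated carbon,,curated reactive-metabolite alert set
methoxy_methyl_para,[CH3]c1ccc(cc1)[OX2][CH3],methoxy and methyl group with three aromatic carbon bonds in between,,curated reactive-metabolite alert set
methyl_aromatic_os,"[CH3]c:c[OX2,SX2]",aromatic carbon bond with methyl and O/S groups,,curated reactive-metabolite alert set
methoxybenzene,[CH3][OX2]c1ccccc1,benzene ring with methoxy group-containing substituent,,curated reactive-metabolite alert set
amine_any,[#7],nitrogen-containing compound,decomposed,curated reactive-metabolite alert set
benzene,c1ccccc1,benzene,decomposed,curated reactive-metabolite alert set
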