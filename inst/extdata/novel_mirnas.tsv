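mirna	mature_5p	mature_3p	precursor	n_loci	tissues
ssa-mir-7132b	gacuuggucaaagcuccucagc	ugaggcguuuagaacaaguuca	gacuuggucaaagcuccucagcagauguuucagagaauccugaggcguuuagaacaaguuca	4	multiple
ssa-mir-8156	guccugacuguccugacuguc	cugucaugaccguccugacugu	guccugacuguccugacugucuuuaccguacuggcugucaugaccguccugacugu	1	multiple
ssa-mir-8157	uagcacauuacaguacagcugu	acucugugcucugcugugcugu	uagcacauuacaguacagcuguauuguuacugcacuguacucugugcucugcugugcugu	2	multiple
ssa-mir-8158	aagagguuucacacauacaaau	uuuguacgugugaaacuucuucc	aagagguuucacacauacaaauguuaauuuuaaaauacucauuuguacgugugaaacuucuucc	1	multiple
ssa-mir-8159	ucaguaacuggaaucugucccugc	agggccggcugguuacugcgc	ucaguaacuggaaucugucccugcagacacacuguagagcagggccggcugguuacugcgc	1	multiple
ssa-mir-2184	aacaguaagaguuaaugugcug	gcacguaggcucuuacaguaca	aacaguaagaguuaaugugcuggguucucaaucagcacguaggcucuuacaguaca	1	multiple
ssa-mir-8160	agaauaaugccagcagucggcc	ccagcacugguguuauuggga	agaauaaugccagcagucggcccugguuuccuaggggccagcacugguguuauuggga	1	multiple
ssa-mir-8161	agaauaaugccagcagucggcc	ccagcgcugguguuauuggga	agaauaaugccagcagucggccauauugucucaaaggccagcgcugguguuauuggga	2	multiple
ssa-mir-7552b	cuacaauuaaaggauauuucuu	aaauaucuuguaauuguuuggu	cuacaauuaaaggauauuucuugugacugagcauauacggaaauaucuuguaauuguuuggu	2	multiple
ssa-mir-7552a-1	uuacaauuaaaggauauuucuu	aaaugucccuuaauuguuuggc	uuacaauuaaaggauauuucuugcgaaugaaugagagacggaaaugucccuuaauuguuuggc	1	multiple
ssa-mir-7552a-2	uuacaauuaaaggauauuucuu	aaauuucccuuaauuguuuggc	uuacaauuaaaggauauuucuugcgauugaauaugagacggaaauuucccuuaauuguuuggc	1	multiple
ssa-mir-8162	uugucucagaccuguuugugcug	ucacaacggaucugggaucagu	uugucucagaccuguuugugcuguaguuguuaucaggaugucacaacggaucugggaucagu	1	multiple
ssa-mir-8163	uuucugaccaugugaccuggggg	ucaggucacauguucaggaua	uuucugaccaugugaccugggggccgagaguguuuccaccucaggucacauguucaggaua	1	liver
ssa-mir-8164	cagagguauuguaauaucguga	acgauacggcgauaauucugau	cagagguauuguaauaucgugauacuacaauacucaccacgauacggcgauaauucugau	1	multiple
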