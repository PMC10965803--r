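individual_id,sequence,abundance
S00001,CASSVQSATEAFF,32
S00001,CASTAPLTQFF,38
S00001,CASRTLHNLATQFF,17
S00001,CASSSNREVLQFQFF,8
S00001,CASSFSQYF,2
S00001,CASSWTYTF,35
S00001,CASSHTGRWTQYF,5
S00001,CAISRIAEAFF,4
S00002,CASSDFQQEQYF,20
S00002,CASSTAAQVQYF,4
S00002,CASSQANIAVQYF,5
S00002,CASSSAQFF,2
S00002,CASSKKAPQYF,28
S00002,CASREGQYF,6
S00002,CASTSFAYQQYF,16
S00002,CASRTALYEGWVEAFF,3
S00002,CASSQSAESDAQFF,27
S00002,CASRFQGGSYTF,42
S00003,CASREGQYF,2
S00003,CASSSGGIGKQYF,10
S00003,CASSTQAQGQYF,3
S00003,CASSFEAKYAHNQYF,9
S00003,CASSSNRESLQSQFF,3
S00003,CAISGGYGQGQYF,10
S00003,CASTSPKEAYRQYF,27
S00003,CASRSISYQAQFF,8
S00003,CASSEDGQFF,2
S00003,CAISAPEGQYF,16
S00003,CASTWAKTRLGGMQYF,7
S00003,CASRAFQGSVGNQYF,3
S00004,CASSGGQYF,2
S00004,CASREGAYQYF,7
S00004,CASSFEVKYAHNQYF,10
S00004,CASSGEQYF,3
S00004,CASSRRAYQFF,41
S00004,CASRLCPDYYQYF,7
S00004,CASRPPEQYF,2
S00004,CASRHLVQYF,5
S00005,CASTPGGVQAQQYF,31
S00005,CASTDGGVTRQQYF,7
S00005,CASSSTNLQDGRHQYF,2
S00005,CASTDGGVQEQQYF,4
S00005,CASSPSAQLIREEAFF,3
S00005,CASTGLYDRAQFF,2
S00005,CASSRWEQYF,8
S00005,CASRVGEGGGEAFF,2
S00006,CASSATQNSQTQTQFF,3
S00006,CASSHQLVSFYEQFF,2
S00006,CASRVGSTGTQFF,10
S00006,CASRIIQGCQYF,10
S00006,CASTLSTFQNYQYF,7
S00006,CASRIEMPHEFSQQYF,21
S00006,CASRDQHAGSGQYF,2
S00007,CASTYEADSLYQYF,17
S00007,CASRAPPGMEAFF,8
S00007,CASSLEAFF,19
S00007,CASRMLDIGSGEWQYF,7
S00007,CASSSATQYF,14
S00007,CASSICLAYNSQYF,29
S00007,CASSLSQYF,2
S00007,CASSVGYTF,4
S00007,CASSPTSSQFF,5
S00008,CASRFTTGYTF,3
S00008,CASSVPEAFF,2
S00008,CASRSFVGQYF,15
S00008,CASSISGADILQFF,11
S00008,CASRVHGEAFF,4
S00008,CASRLFSSGEEAFF,2
S00008,CASRRFGKTRQYF,2
S00008,CASRDEFPVDEAFF,26
S00008,CASSPISCFRTHGQFF,2
S00008,CASRPQNGDSLLRQFF,21
S00009,CASTSKSGPGMQYF,10
S00009,CASRAPPLMEAFF,18
S00009,CASSQPAVLCFQYF,36
S00009,CASSSTNLQDGRHQYF,4
S00009,CASSMCTSQLQFF,2
S00009,CASSTDTSRIQFF,2
S00009,CASSTMLNQIGQFF,2
S00009,CASRNQVHLQYF,5
S00009,CASSWDGPQFF,18
S00009,CASSGGGWGECGVQYF,24
S00009,CASRYQVVQQFF,14
S00009,CASSCTQFF,6
S00010,CASSIITSTSLQFF,12
S00010,CASRLDQYF,50
S00010,CASRECQYF,7
S00010,CASSDPLQFF,3
S00010,CASSGLTLQYF,4
S00010,CASSRPEEEAFF,5
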