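4278|ENG|||||Y|1||||NDFRT|FN|N0000006373|Famotidine [Chemical/Ingredient]||N||
44|ENG|||||Y|2||||NDFRT|FN|N0000147595|Mesna||N||
45|ENG|||||Y|3||||NDFRT|FN|N0000156948|MESNA 100MG/ML INJ [VA Product]||N||
46|ENG|||||Y|4||||NDFRT|FN|N0000006244|Fatty Acids, Omega-3 [Chemical/Ingredient]||N||
47|ENG|||||Y|5||||NDFRT|FN|N000158434|SILICON DIOXIDE [VA Product]||N||
48|ENG|||||Y|6||||NDFRT|FN|N0000175583|Omega-3 Fatty Acid [EPC]||N||
4278|ENG|||||Y|500||||RXNORM|IN|4278|Famotidine||N||
4278|ENG|||||Y|501||||RXNORM|SY|4278|famotidine||N||
47|ENG|||||Y|502||||RXNORM|SCD|47|SILICON DIOXIDE tablet||N||
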