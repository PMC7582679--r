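compound_id,smiles,name,source
1,O=C(CCc1ccc(O)cc1)c1c(O)cc(O)cc1O,phloretin,natural
2,O=C(CCc1ccc(O)c(O)c1)c1c(O)cc(O)cc1O,3-hydroxyphloretin,natural
3,O=C(CCc1ccccc1)c1c(O)cc(OC)cc1O,"2',6'-dihydroxy-4'-methoxydihydrochalcone",natural
4,O=C(CCc1ccc(O)cc1)c1c(O)cc(OC)cc1O,asebogenin,natural
5,O=C(CCc1ccc(OC)cc1)c1c(O)cc(OC)cc1O,calomelanen,natural
6,O=C(CCc1ccc(O)c(O)c1)c1c(O)cc(O[C@@H]2O[C@H](CO)[C@@H](O)[C@H](O)[C@H]2O)cc1O,sieboldin,natural
7,O=C(CCc1ccc(O)cc1)c1c(O)cc(O)cc1O[C@@H]1O[C@H](CO)[C@@H](O)[C@H](O)[C@H]1O,phloridzin,natural
8,O=C(CCc1ccc(O)cc1)c1c(O)cc(O[C@@H]2O[C@H](CO)[C@@H](O)[C@H](O)[C@H]2O)cc1O,trilobatin,natural
9,O=C(CCc1ccc(O)cc1)c1c(O)cc(O)cc1O[C@@H]1O[C@H](CO[C@@H]2O[C@@H](C)[C@H](O)[C@H](O)[C@H]2O)[C@@H](O)[C@H](O)[C@H]1O,phloretin-2'-xyloglucoside,natural
10,O=C(CCc1ccc(OC)c(O)c1)c1c(O)cc(O[C@@H]2O[C@H](CO)[C@@H](O)[C@H](O)[C@H]2O[C@@H]2O[C@@H](C)[C@H](O)[C@H](O)[C@H]2O)cc1O,neohesperidin dihydrochalcone,semisynthetic
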