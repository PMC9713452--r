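5e5a581f2b801d47b07b1f4b0b5ee610  annotations.tsv
8eab7ac917b8439bfe42ffd9d529cf2a  config.yaml
041bf52a181878a9c1f6c7f20e3ab93b  docking_tb_alignment.fasta
b845ac41715e9be84086714273fb1fb7  expected_conserved.tsv
b48438756b64a48cfa142324bb63f0c7  mutations.tsv
2e85790828750d5bbfdf168f95b82c1b  partner_domains.tsv
e32e1fced692b0e120b9ac0b36035e86  precursors.fasta
a011d75cc55c3f2554ab5d48139e2c46  prodomain_alignment.fasta
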