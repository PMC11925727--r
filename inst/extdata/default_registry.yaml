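parts:
- name: hh_minimal
  role: hh_template
  sequence: NNNNNNCTGATGAGTCCGTGAGGACGAAACGAGTAAGCTCGTC
- name: hdv_genomic
  role: hdv
  sequence: GGCCGGCATGGTCCCAGCCTCCTCGCTGGCGCCGGCTGGGCAACATGCTTCGGCATGGCGAATGGGAC
- name: sp_sgrna_scaffold
  role: cas9_scaffold
  sequence: GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCGTTATCAACTTGAAAAAGTGGCACCGAGTCGGTGC
- name: lb_direct_repeat
  role: cas12a_direct_repeat
  sequence: TAATTTCTACTAAGTGTAGAT
enzymes:
- name: SapI
  recognition: GCTCTTC
  cut_offset_top: 1
  cut_offset_bottom: 4
- name: LguI
  recognition: GCTCTTC
  cut_offset_top: 1
  cut_offset_bottom: 4
- name: BbsI
  recognition: GAAGAC
  cut_offset_top: 2
  cut_offset_bottom: 6
overhang_sets:
- name: sapi_pair
  overhangs:
  - AAT
  - GCA
- name: bbsi_pair
  overhangs:
  - AATG
  - GCAA
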