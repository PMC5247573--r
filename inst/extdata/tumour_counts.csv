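sample_id,n_rois,n_mutant,n_wildtype,clinical,clinical_detail
A,14,82,345,Mutant,G-12S 18%
E,9,3,546,Wild type,Wild type
F,7,50,262,Mutant,G-12V 37%
I,8,140,255,Mutant,G-12V (ratio NA)
E1,6,51,706,Wild type,Wild type
J,6,64,857,Wild type,Wild type
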