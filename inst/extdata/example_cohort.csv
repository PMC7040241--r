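# format_version: 1
"nodule_id","histology","truth","us_pattern","alterations"
"N001","PTC","MALIGNANT","HIGH",""
"N002","PTCFV","MALIGNANT","INTERMEDIATE","BRAF:p.Val600Glu"
"N003","ADENOMATOID_NODULE","BENIGN","LOW",""
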