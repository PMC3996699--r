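# Key enzymes of butyrate formation from acetyl-CoA, including both routes
# for the final conversion of butyryl-CoA to butyrate.
name: butyrate_pathway
genes:
  - acetyl_CoA_acetyltransferase
  - hydroxybutyryl_CoA_dehydratase
  - butyryl_CoA_dehydrogenase
  - butyrate_kinase
  - phosphate_butyryltransferase
  - butyryl_CoA_acetate_CoA_transferase
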