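# Glycoside hydrolases and sulfatases putatively involved in degradation of
# O-linked mucin glycoproteins. Edit freely: panels are conventions, not
# constants; identifiers must resolve against the function-gene table.
name: mucin_degradation
genes:
  - beta_hexosaminidase
  - alpha_mannosidase
  - beta_mannosidase
  - neuraminidase_sialidase
  - beta_galactosidase
  - sulfatase
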