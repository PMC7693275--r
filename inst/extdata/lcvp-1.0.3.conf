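# default dialect for the v1.0.3 backbone export; equivalent to the
# built-in lcvp_dialect().  Override keys as needed for file-version drift.
label = lcvp-1.0.3
col.input_name = Input_Taxon, Input.Taxon, Input Taxon, InputTaxon
col.status = Status, status
col.accepted_name = Output_Taxon, Output.Taxon, Output Taxon, OutputTaxon
col.family = Family, family
col.order = Order, order
col.tpl_comparison = PL_comparison, PL.comparison, TPL_comparison, TPL.comparison
status.accepted = accepted
status.synonym = synonym
status.unresolved = unresolved
status.valid = accepted
status.invalid = synonym
status.comb.ined. = synonym
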