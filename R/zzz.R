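.datatable.aware <- TRUE

utils::globalVariables(c(
  "fill_date", "drug_name", "service_date", "admission_date",
  "discharge_date", "patient_id", "setting", "day", "adm_day", "dis_day",
  "dx1", "dx2", "dx3", "paid", ":="))
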