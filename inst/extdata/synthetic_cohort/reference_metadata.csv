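sample_id,group,gestational_age,run_day,storage_time_months,maternal_age,ethnicity,smoker,replicate_group
REF001,reference,,ref_day,1.0692571755498648,,,,
REF002,reference,,ref_day,5.547478065825999,,,,
REF003,reference,,ref_day,2.4243086334317923,,,,
REF004,reference,,ref_day,9.893873646855354,,,,
REF005,reference,,ref_day,35.893251836299896,,,,
REF006,reference,,ref_day,18.633903002366424,,,,
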