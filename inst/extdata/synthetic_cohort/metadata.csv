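sample_id,group,gestational_age,run_day,storage_time_months,maternal_age,ethnicity,smoker,replicate_group
P001,pregnant,10w4d,day2,31.22811869625002,22,african_american,FALSE,
P002,pregnant,10w4d,day1,5.68515489064157,20,white,FALSE,
P003,pregnant,14w5d,day1,10.473377930000424,19,african_american,FALSE,
P004,pregnant,15w6d,day2,7.035285995341837,24,african_american,FALSE,
P005,pregnant,14w4d,day1,10.823469439521432,27,african_american,TRUE,
P006,pregnant,9w4d,day2,10.654113706201315,18,african_american,FALSE,
P007,pregnant,14w0d,day2,20.10111646167934,22,african_american,TRUE,
N001,non_pregnant,,day1,2.5837898310273886,33,african_american,FALSE,
N002,non_pregnant,,day2,33.16197865549475,34,white,TRUE,
N003,non_pregnant,,day1,9.251782824285328,29,white,FALSE,
N004,non_pregnant,,day1,2.1193851800635457,19,white,FALSE,
N005,non_pregnant,,day2,33.526427677832544,22,white,FALSE,
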