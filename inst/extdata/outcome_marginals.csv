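category,count
Signs/symptoms reflecting continuation/end of condition,3639
Adverse events,2368
Infection/onset of new acute/chronic disease,2215
Biological markers,2071
General physical health,1921
Obstetric outcomes,1477
All-cause mortality,1278
Hospital stay/process measures,1158
Quality of life/functioning,958
Pain,802
Mental health outcomes,743
Surgical/device related success/failure,737
Withdrawals/dropouts,643
Internal structure,504
Major morbidity event,502
Composite (at least 1 non-mortality/morbidity),460
Composite (mortality/morbidity only),224
Cause-specific mortality,194
Consumption,190
External structure,160
Other,94
Satisfaction with care,86
Resource use,29
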