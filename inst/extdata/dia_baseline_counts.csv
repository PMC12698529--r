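block,level,n
sex,Female,139084
sex,Male,18433
sex,Unknown,23532
reporting_year,2004-2010,13601
reporting_year,2011-2015,29375
reporting_year,2016-2020,87379
reporting_year,2021-2024,50694
region,United States,134199
region,Canada,13238
region,United Kingdom,5380
region,France,5136
region,Germany,3168
occupation,Consumer,101167
occupation,Physician,24722
occupation,Pharmacist,21587
occupation,Lawyer,15753
occupation,Other health-professional,12092
occupation,Unknown,5728
severity,Non-serious,96511
severity,Serious,84538
outcome,Life-threatening,3769
outcome,Hospitalization,18354
outcome,Disability,9746
outcome,Death,3544
outcome,Congenital anomaly,692
outcome,Required intervention,721
outcome,Other serious,72151
age,Unknown,74984
weight,Unknown,129508
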