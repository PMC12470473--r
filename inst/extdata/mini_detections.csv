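code,albopictus_field_year,albopictus_field_source,albopictus_citizen_year,aegypti_field_year,aegypti_field_source,aegypti_citizen_year,japonicus_field_year,japonicus_field_source,japonicus_citizen_year
08001,2008,own data,,,,,,,
08019,2005,own data,2014,,,,,,
08279,2006,own data,2015,,,,,,
17079,,,2016,,,,,,
17118,2019,own data,2019,,,,,,
46250,2015,own data,2015,,,,,,
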