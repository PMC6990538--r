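# Mean blood pressure (mmHg) and body mass index (kg/m2) by examination year,
# sex and age group, Student Health Service, Hong Kong. Systolic/diastolic BP
# cover 1999-2014 (ages 9-18); BMI covers 1996-2014 (ages 6-18). NA = outcome
# not collected that year.
year,participation_rate,sbp_boys_9_11,sbp_girls_9_11,sbp_boys_12_18,sbp_girls_12_18,dbp_boys_9_11,dbp_girls_9_11,dbp_boys_12_18,dbp_girls_12_18,bmi_boys_9_11,bmi_girls_9_11,bmi_boys_12_18,bmi_girls_12_18
1996,86.3,NA,NA,NA,NA,NA,NA,NA,NA,17.2,16.7,18.9,19.0
1997,74.7,NA,NA,NA,NA,NA,NA,NA,NA,17.0,16.5,19.6,19.6
1998,77.9,NA,NA,NA,NA,NA,NA,NA,NA,17.2,16.6,19.5,19.4
1999,76.0,104.6,104.2,115.0,108.9,60.5,60.2,63.5,62.7,17.3,16.6,19.5,19.4
2000,75.6,104.8,104.4,115.6,108.6,59.5,59.3,62.8,62.0,17.3,16.6,19.6,19.4
2001,76.8,103.9,104.0,115.4,108.3,58.8,58.8,62.1,61.3,17.3,16.7,19.6,19.4
2002,79.0,103.7,103.7,115.6,108.1,58.8,58.7,62.4,61.3,17.3,16.7,19.5,19.3
2003,80.2,102.3,102.7,114.8,107.6,58.1,58.3,61.9,60.9,17.5,16.8,19.7,19.4
2004,81.5,101.9,101.9,113.7,106.9,57.9,58.0,61.5,60.7,17.5,16.8,19.8,19.5
2005,78.6,102.0,102.1,113.3,106.6,57.8,58.0,61.2,60.3,17.6,16.9,19.8,19.5
2006,83.6,102.7,102.1,113.9,107.1,58.6,58.4,61.9,61.0,17.7,16.9,19.9,19.6
2007,87.0,102.5,102.7,114.3,107.6,58.6,58.9,62.0,61.2,17.8,17.0,19.9,19.6
2008,87.5,102.7,102.1,114.0,107.2,58.6,58.5,61.8,61.0,17.9,17.1,20.0,19.7
2009,87.1,103.0,102.8,113.8,107.4,58.8,58.8,61.8,61.1,18.0,17.1,20.0,19.7
2010,95.1,103.6,102.8,113.9,107.6,59.3,59.0,62.0,61.3,17.8,17.0,20.2,19.8
2011,89.0,103.1,102.2,115.2,107.9,58.8,58.6,62.3,61.3,17.8,16.9,20.3,19.9
2012,88.3,103.6,102.6,115.6,107.9,59.2,58.8,62.3,61.3,17.5,16.7,20.3,19.9
2013,90.0,103.6,102.8,115.3,108.2,59.3,59.0,62.4,61.5,17.4,16.6,20.3,20.0
2014,90.8,103.4,102.9,114.9,108.1,59.2,59.1,62.6,61.6,17.1,16.3,20.3,19.9
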