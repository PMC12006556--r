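# NHS/PSS unit costs, 2021/22 price year. Admission episode costs are HRG
# weighted averages (2015/16 reference costs with excess-bed-day and length-
# of-stay data, uprated to 2021/22 upstream of this file); the engine does no
# inflation arithmetic.
price_year: "2021/22"
sampling:
  tissue: 20
  swab: 12
  bone: 124
contacts:
  gp: 38
  practice_nurse: 13
  district_nurse: 54
  foot_clinic: 93
  outpatient: 183
  ae: 144
admissions:
  major_amputation:        {cost_per_episode: 11723, avg_los_days: 19, excess_bed_day: 313}
  minor_amputation:        {cost_per_episode: 5385,  avg_los_days: 9,  excess_bed_day: 328}
  revascularisation:       {cost_per_episode: 8329,  avg_los_days: 7,  excess_bed_day: 368}
  osteotomy_ipj:           {cost_per_episode: 2506,  avg_los_days: 2,  excess_bed_day: 373}
  surgical_debridement:    {cost_per_episode: 817,   avg_los_days: 1,  excess_bed_day: 0}
  arthroplasty:            {cost_per_episode: 3969,  avg_los_days: 2,  excess_bed_day: 389}
  osteomyelitis:           {cost_per_episode: 3905,  avg_los_days: 8,  excess_bed_day: 314}
  removal_external_frame:  {cost_per_episode: 2034,  avg_los_days: 2,  excess_bed_day: 357}
  gastrocnemius_release:   {cost_per_episode: 2034,  avg_los_days: 2,  excess_bed_day: 357}
  cellulitis:              {cost_per_episode: 1791,  avg_los_days: 6,  excess_bed_day: 1791}
  other:                   {cost_per_episode: 2637,  avg_los_days: 7,  excess_bed_day: 295}
post_amputation_cost: 529
antibiotics:
  - {drug: amoxicillin, form: 500 mg capsule, unit_cost: 0.21}
  - {drug: benzylpenicillin, form: 600 mg vial, unit_cost: 2.89}
  - {drug: ceftazidime, form: 2 g, unit_cost: 16.43}
  - {drug: ceftriaxone, form: 250 mg vial, unit_cost: 2.37}
  - {drug: ceftriaxone, form: 1 g vial, unit_cost: 8.61}
  - {drug: ceftriaxone, form: 2 g vial, unit_cost: 19.00}
  - {drug: clindamycin, form: 300 mg capsule, unit_cost: 1.03}
  - {drug: clindamycin, form: 150 mg/mL ampoule, unit_cost: 8.77}
  - {drug: clarithromycin, form: 500 mg tablet, unit_cost: 0.65}
  - {drug: clarithromycin, form: 500 mg vial, unit_cost: 10.85}
  - {drug: ciprofloxacin, form: 500 mg tablet, unit_cost: 0.25}
  - {drug: co-amoxiclav, form: 500 mg/125 mg tablet, unit_cost: 0.39}
  - {drug: co-amoxiclav, form: 500 mg/100 mg vial, unit_cost: 1.30}
  - {drug: co-trimoxazole, form: 160 mg/800 mg tablet, unit_cost: 0.25}
  - {drug: doxycycline, form: 100 mg capsule, unit_cost: 0.16}
  - {drug: ertapenem, form: 1 g powder vial, unit_cost: 31.65}
  - {drug: erythromycin, form: 500 mg tablet, unit_cost: 0.45}
  - {drug: erythromycin, form: 1 g powder vial, unit_cost: 22.46}
  - {drug: flucloxacillin, form: 500 mg capsule, unit_cost: 0.16}
  - {drug: flucloxacillin, form: 500 mg vial, unit_cost: 9.66}
  - {drug: fusidic acid, form: 500 mg vial, unit_cost: 21.95}
  - {drug: gentamicin, form: 40 mg/mL vial, unit_cost: 1.38}
  - {drug: linezolid, form: 600 mg capsule, unit_cost: 35.48}
  - {drug: meropenem, form: 500 mg, unit_cost: 9.87}
  - {drug: metronidazole, form: 400 mg, unit_cost: 0.20}
  - {drug: metronidazole, form: 5 mg/mL infusion bag, unit_cost: 3.49}
  - {drug: phenoxymethylpenicillin, form: 250 mg tablet, unit_cost: 0.12}
  - {drug: piperacillin-tazobactam, form: 4 g/500 mg, unit_cost: 12.18}
  - {drug: rifampicin, form: 600 mg, unit_cost: 9.20}
  - {drug: teicoplanin, form: 200 mg, unit_cost: 6.55}
  - {drug: tigecycline, form: 50 mg, unit_cost: 29.08}
  - {drug: trimethoprim, form: 200 mg, unit_cost: 0.27}
default_duration_days: 7
default_units_per_day: 3
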