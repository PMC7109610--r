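# Default MS-HRS valuation tables: German unit costs at the 2011 price level.
# All monetary values are EUR. Replace this file (or pass your own via
# mshrs_valuation(path)) to localize the costing engine; price tags must be
# updated and adapted to local levels before reuse in another setting.
reference_year: 2011
currency: EUR

unit_costs:
  inpatient_per_day:
    source: "Standardized German unit costs, inpatient care per day, 2011"
    hospital: 593.04
    rehabilitation: 121.85
    nursing: 69.80
  day_admission_per_day:
    source: "Standardized German unit costs, day admissions per day, 2011"
    hospital: 385.48
    rehabilitation: 46.68
    nursing: 46.15
  consultation_per_contact:
    source: "Standardized German unit costs per ambulant contact, 2011"
    # Derived valuations (source components not published, kept as constants):
    #  - nurse: rated with the lowest available monetary contact value
    #  - psychologist: valued as a psychotherapist visit
    #  - other_specialist: mean of the example specialties (e.g. psychiatrist,
    #    urologist, ophthalmologist)
    general_practitioner: 20.06
    neurologist: 44.72
    other_specialist: 34.73
    nurse: 16.42
    physiotherapist: 16.42
    psychologist: 78.08
    occupational_therapist: 37.51
    optician: 34.78
    speech_therapist: 38.59
    acupuncturist: 18.24
    other_alternative: 27.40
  examination_per_unit:
    source: "Approximated from the physicians' fee schedule, 2011"
    # 'other' is a published aggregate constant; its derivation is not stated.
    mri: 120.21
    ct: 73.78
    lumbar_puncture: 38.90
    blood_test: 1.10
    other: 60.66
  professional_care_per_hour: 27.57
  informal_care_per_hour: 21.09
  disability_pension_cap_per_year: 42045.38

labor_market:
  source: "German official labor statistics, 2011"
  annual_work_hours: 1406.2
  annual_work_days: 233
  hourly_labor_cost: 29.90
  informal_care_cap_hours_per_week: 60
  standard_week_days: 5

dmt_annual_costs:
  source: "Defined daily dose net costs x 365, statutory discounts applied"
  # Rows are calendar years; NA marks a drug not yet marketed that year.
  years: [2010, 2011, 2012, 2013, 2014, 2015, 2016, 2017]
  AVO: [18069.27, 18611.35, 18182.19, 17981.00, 19437.31, 19333.96, 19247.42, 18865.10]
  REB: [22626.46, 23305.25, 22900.46, 22765.35, 24432.98, 24155.25, 23987.27, 23529.38]
  BET: [17977.14, 18516.45, 18132.07, 17815.29, 17601.95, 17517.70, 17384.09, 17047.81]
  EXT: [15528.45, 15994.30, 15604.68, 15431.93, 15441.48, 15370.25, 14680.25, 15715.49]
  COP: [16623.45, 17122.15, 16377.93, 16197.00, 17035.61, 16733.32, 16648.48, 16352.26]
  GIL: [.na, 26698.58, 25907.56, 22571.44, 18965.36, 20393.73, 21516.72, 20784.68]
  TYS: [24625.10, 25363.85, 24586.58, 24214.41, 26194.92, 24280.75, 23321.06, 22902.02]

price_adjustment:
  source: "Conventional cost inflation; 2011 EUR/USD annual average"
  default_inflation_rate: 0.02
  eur_usd_rate: 1.392
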