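# Oral-anticoagulant use in atrial fibrillation, 2005-2018:
# cohort and drug groups for the trend replication machinery.
name: af-oac-trend
filter:
  include_icd: ["I48"]
  exclude_icd: ["I05", "I06", "I07", "I08", "I09",
                "I34", "I35", "I36", "I37", "Q22", "Q23",
                "I26", "I82"]
  date_start: "2005-01-01"
  date_end: "2019-01-01"
  age_min: 30
  age_max: 100
groups:
  - label: VKA
    atc_prefix: B01AA
  - label: Dabigatran
    atc_prefix: B01AE07
  - label: Rivaroxaban
    atc_prefix: B01AF01
  - label: Apixaban
    atc_prefix: B01AF02
  - label: Beta blockers
    atc_prefix: C07
periods:
  - label: "2005-2007"
    start: "2005-01-01"
    end: "2008-01-01"
  - label: "2008-2010"
    start: "2008-01-01"
    end: "2011-01-01"
  - label: "2011-2013"
    start: "2011-01-01"
    end: "2014-01-01"
  - label: "2014-2016"
    start: "2014-01-01"
    end: "2017-01-01"
  - label: "2017-2018"
    start: "2017-01-01"
    end: "2019-01-01"
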