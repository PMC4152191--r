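{
  "abs_blue": {
    "scenario": "absenteeism",
    "occupation": "blue",
    "horizon": 4,
    "cost_lpt": 5158.41914771196,
    "cost_turnover": 748.063047963679,
    "cost_service": 436.226305077432,
    "cost_antidepressant": 161.76753482337,
    "cost_total": 6504.47603557644,
    "qalys": 0.715380585057563
  },
  "abs_white": {
    "scenario": "absenteeism",
    "occupation": "white",
    "horizon": 4,
    "cost_lpt": 6525.40335053278,
    "cost_turnover": 940.039046543298,
    "cost_service": 436.322905978919,
    "cost_antidepressant": 161.803357719682,
    "cost_total": 8063.56866077468,
    "qalys": 0.715526003467458
  },
  "pres_blue": {
    "scenario": "presenteeism",
    "occupation": "blue",
    "horizon": 4,
    "cost_lpt": 1304.43912706368,
    "cost_turnover": 655.793957944689,
    "cost_service": 438.532494971017,
    "cost_antidepressant": 162.622748389305,
    "cost_total": 2561.38832836869,
    "qalys": 0.738293125331109
  },
  "pres_white": {
    "scenario": "presenteeism",
    "occupation": "white",
    "horizon": 4,
    "cost_lpt": 1650.11454478932,
    "cost_turnover": 824.089133866165,
    "cost_service": 438.627224893364,
    "cost_antidepressant": 162.657877462985,
    "cost_total": 3075.48878101184,
    "qalys": 0.738438113233036
  }
}
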