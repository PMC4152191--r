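{
  "abs_blue": {
    "cost_total": {
      "mean": 6504.97441667758,
      "low": 4525.56154655571,
      "high": 9261.69674661403
    },
    "cost_lpt": {
      "mean": 5169.29721798615,
      "low": 3270.12600359391,
      "high": 7929.39590940451
    },
    "cost_turnover": {
      "mean": 740.284513266308,
      "low": 422.016666104463,
      "high": 1194.04305700084
    },
    "cost_service": {
      "mean": 435.304559514316,
      "low": 330.449964363362,
      "high": 574.04465816988
    },
    "cost_antidepressant": {
      "mean": 160.088125910801,
      "low": 113.069355572319,
      "high": 210.366169846129
    },
    "qalys": {
      "mean": 0.715303825526287,
      "low": 0.683741637407274,
      "high": 0.745404640199419
    }
  },
  "abs_white": {
    "cost_total": {
      "mean": 8064.95493984944,
      "low": 5557.99430256305,
      "high": 11547.2651374554
    },
    "cost_lpt": {
      "mean": 6539.16581253647,
      "low": 4136.78936404115,
      "high": 10030.6598432319
    },
    "cost_turnover": {
      "mean": 930.264560185149,
      "low": 530.316440495191,
      "high": 1500.44428649467
    },
    "cost_service": {
      "mean": 435.400985790525,
      "low": 330.521374967666,
      "high": 574.176057041501
    },
    "cost_antidepressant": {
      "mean": 160.123581337299,
      "low": 113.093083408079,
      "high": 210.413600107661
    },
    "qalys": {
      "mean": 0.715449276428895,
      "low": 0.683886856840281,
      "high": 0.745562686133015
    }
  },
  "pres_blue": {
    "cost_total": {
      "mean": 2554.57726693556,
      "low": 1929.75002035947,
      "high": 3371.99850684164
    },
    "cost_lpt": {
      "mean": 1307.01825867405,
      "low": 830.058271219818,
      "high": 1993.76711164755
    },
    "cost_turnover": {
      "mean": 649.015940080591,
      "low": 368.313950043567,
      "high": 1048.22082548245
    },
    "cost_service": {
      "mean": 437.608086140371,
      "low": 332.23081092203,
      "high": 577.110155386615
    },
    "cost_antidepressant": {
      "mean": 160.934982040555,
      "low": 113.679639590398,
      "high": 211.375033000217
    },
    "qalys": {
      "mean": 0.738221345319504,
      "low": 0.70296092008825,
      "high": 0.768166932927719
    }
  },
  "pres_white": {
    "cost_total": {
      "mean": 3067.6218398086,
      "low": 2286.94188368029,
      "high": 4086.16876271907
    },
    "cost_lpt": {
      "mean": 1653.3775407791,
      "low": 1050.03555045634,
      "high": 2522.07468043501
    },
    "cost_turnover": {
      "mean": 815.571909412329,
      "low": 462.831360512104,
      "high": 1317.20100411843
    },
    "cost_service": {
      "mean": 437.702639959614,
      "low": 332.305761457715,
      "high": 577.238559363592
    },
    "cost_antidepressant": {
      "mean": 160.969749657563,
      "low": 113.703060158175,
      "high": 211.421382498783
    },
    "qalys": {
      "mean": 0.73836635430862,
      "low": 0.70309386402739,
      "high": 0.768323115086396
    }
  }
}
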