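{
  "seed": 60101,
  "config": {
    "n_patients": [5, 5],
    "weeks": [-3, -2, -1, 0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11],
    "fixed_effects": {
      "improving": [3.837, 0.039],
      "nonimproving": [3.598, 0.006]
    },
    "sd_intercept": 0.8,
    "sd_slope": 0.05,
    "re_correlation": 0,
    "sd_resid": 0.6,
    "tokens_mean": 40,
    "tokens_size": 5,
    "phq": {
      "baseline_mean": 13.4,
      "baseline_sd": 4.9,
      "slope": [-0.75, -0.1],
      "resid_sd": 2
    },
    "rates": {
      "i": [0.055, 0.0012],
      "we": [0.01, -0.0003],
      "posemo": [0.02, -0.0006],
      "negemo": [0.022, 0.0009],
      "sadness": [0.008, 0.0004],
      "body": [0.006, 0.0002],
      "health": [0.007, 0.0003],
      "sexual": [0.0015, 0],
      "ingestion": [0.004, 0]
    },
    "seed": 1
  },
  "patients": [
    {
      "patient_id": "P-imp-00001",
      "group": "improving",
      "gamma0": 0.515057790200881,
      "gamma1": -0.0133361982608094,
      "phq_baseline": 14.1035701250846,
      "intercept": 3.837,
      "slope": 0.039
    },
    {
      "patient_id": "P-imp-00002",
      "group": "improving",
      "gamma0": 0.494886016343512,
      "gamma1": 0.014432097103445,
      "phq_baseline": 12.471196923046,
      "intercept": 3.837,
      "slope": 0.039
    },
    {
      "patient_id": "P-imp-00003",
      "group": "improving",
      "gamma0": 1.89227447390673,
      "gamma1": 0.0401696877955675,
      "phq_baseline": 11.4468062760056,
      "intercept": 3.837,
      "slope": 0.039
    },
    {
      "patient_id": "P-imp-00004",
      "group": "improving",
      "gamma0": -1.48835984580158,
      "gamma1": 0.0197121983491681,
      "phq_baseline": 13.0294116825726,
      "intercept": 3.837,
      "slope": 0.039
    },
    {
      "patient_id": "P-imp-00005",
      "group": "improving",
      "gamma0": 1.11971542437087,
      "gamma1": -0.0225971945982111,
      "phq_baseline": 12.4488724245445,
      "intercept": 3.837,
      "slope": 0.039
    },
    {
      "patient_id": "P-non-00001",
      "group": "nonimproving",
      "gamma0": -0.994535953359271,
      "gamma1": -0.102869105580316,
      "phq_baseline": 15.4523494084193,
      "intercept": 3.598,
      "slope": 0.006
    },
    {
      "patient_id": "P-non-00002",
      "group": "nonimproving",
      "gamma0": 0.006244421965322,
      "gamma1": -0.0697140010119117,
      "phq_baseline": 14.7087119150443,
      "intercept": 3.598,
      "slope": 0.006
    },
    {
      "patient_id": "P-non-00003",
      "group": "nonimproving",
      "gamma0": -0.258688067496633,
      "gamma1": -0.077547438720813,
      "phq_baseline": 10.9454144260428,
      "intercept": 3.598,
      "slope": 0.006
    },
    {
      "patient_id": "P-non-00004",
      "group": "nonimproving",
      "gamma0": 0.308912726428441,
      "gamma1": 0.0677472495113133,
      "phq_baseline": 11.7905137108337,
      "intercept": 3.598,
      "slope": 0.006
    },
    {
      "patient_id": "P-non-00005",
      "group": "nonimproving",
      "gamma0": 0.458008389476035,
      "gamma1": -0.0219154901202618,
      "phq_baseline": 12.4740143291252,
      "intercept": 3.598,
      "slope": 0.006
    }
  ]
}
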