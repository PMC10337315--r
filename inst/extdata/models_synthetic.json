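[
  {
    "name": "A",
    "intercept": 2.1,
    "coef_ct": -2.8,
    "feature_name": "glcm_joint_maximum",
    "coef_feature": 1.6
  },
  {
    "name": "B",
    "intercept": 2.4,
    "coef_ct": -2.8,
    "feature_name": "stat_median_absolute_deviation",
    "coef_feature": -2.0
  },
  {
    "name": "C",
    "intercept": 4.5,
    "coef_ct": -2.9,
    "feature_name": "glcm_joint_entropy",
    "coef_feature": -0.45
  },
  {
    "name": "D",
    "intercept": 3.8,
    "coef_ct": -2.8,
    "feature_name": "glcm_sum_entropy",
    "coef_feature": -0.55
  },
  {
    "name": "E",
    "intercept": 1.9,
    "coef_ct": -2.7,
    "feature_name": "glcm_angular_second_moment",
    "coef_feature": 2.2
  },
  {
    "name": "F",
    "intercept": 2.0,
    "coef_ct": -2.8,
    "feature_name": "glcm_inverse_variance",
    "coef_feature": 1.2
  }
]
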