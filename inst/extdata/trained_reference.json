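{
  "schema_version": 1,
  "note": "trained reference parameters",
  "attributes": [
    {
      "name": "ARTUL",
      "labels": ["S", "N", "B"],
      "ref_values": [4, 8, 12]
    },
    {
      "name": "RTT",
      "labels": ["S", "N", "L"],
      "ref_values": [5, 10, 15]
    },
    {
      "name": "MAMS",
      "labels": ["S", "N", "H"],
      "ref_values": [5, 8, 11]
    }
  ],
  "attribute_weights": [1, 1, 1],
  "grade_labels": ["I", "II", "III", "IV"],
  "grade_utilities": [1, 2, 3, 4],
  "rules": [
    {
      "antecedent": ["S", "S", "S"],
      "theta": 1,
      "beliefs": [0.83499999999999996, 0.14999999999999999, 0.012999999999999999, 0]
    },
    {
      "antecedent": ["S", "S", "N"],
      "theta": 1,
      "beliefs": [0.81399999999999995, 0.17599999999999999, 0.01, 0]
    },
    {
      "antecedent": ["S", "S", "H"],
      "theta": 1,
      "beliefs": [0.72299999999999998, 0.23699999999999999, 0.029999999999999999, 0.01]
    },
    {
      "antecedent": ["S", "N", "S"],
      "theta": 1,
      "beliefs": [0.81200000000000006, 0.11700000000000001, 0.064000000000000001, 0.0070000000000000001]
    },
    {
      "antecedent": ["S", "N", "N"],
      "theta": 1,
      "beliefs": [0.83699999999999997, 0.105, 0.047, 0.010999999999999999]
    },
    {
      "antecedent": ["S", "N", "H"],
      "theta": 1,
      "beliefs": [0.64300000000000002, 0.34799999999999998, 0.0080000000000000002, 0.001]
    },
    {
      "antecedent": ["S", "L", "S"],
      "theta": 1,
      "beliefs": [0.48899999999999999, 0.377, 0.10299999999999999, 0.031]
    },
    {
      "antecedent": ["S", "L", "N"],
      "theta": 1,
      "beliefs": [0.46600000000000003, 0.27900000000000003, 0.22800000000000001, 0.027]
    },
    {
      "antecedent": ["S", "L", "H"],
      "theta": 1,
      "beliefs": [0.027, 0.81299999999999994, 0.13200000000000001, 0.028000000000000001]
    },
    {
      "antecedent": ["N", "S", "S"],
      "theta": 1,
      "beliefs": [0.77400000000000002, 0.19600000000000001, 0.029999999999999999, 0]
    },
    {
      "antecedent": ["N", "S", "N"],
      "theta": 1,
      "beliefs": [0.496, 0.38600000000000001, 0.107, 0.010999999999999999]
    },
    {
      "antecedent": ["N", "S", "H"],
      "theta": 1,
      "beliefs": [0.31900000000000001, 0.376, 0.245, 0.059999999999999998]
    },
    {
      "antecedent": ["N", "N", "S"],
      "theta": 1,
      "beliefs": [0.19700000000000001, 0.63100000000000001, 0.123, 0.049000000000000002]
    },
    {
      "antecedent": ["N", "N", "N"],
      "theta": 1,
      "beliefs": [0.088999999999999996, 0.217, 0.59699999999999998, 0.097000000000000003]
    },
    {
      "antecedent": ["N", "N", "H"],
      "theta": 1,
      "beliefs": [0.012999999999999999, 0.32100000000000001, 0.56399999999999995, 0.10199999999999999]
    },
    {
      "antecedent": ["N", "L", "S"],
      "theta": 1,
      "beliefs": [0.0030000000000000001, 0.064000000000000001, 0.877, 0.056000000000000001]
    },
    {
      "antecedent": ["N", "L", "N"],
      "theta": 1,
      "beliefs": [0.032000000000000001, 0.0050000000000000001, 0.89900000000000002, 0.064000000000000001]
    },
    {
      "antecedent": ["N", "L", "H"],
      "theta": 1,
      "beliefs": [0.001, 0.0060000000000000001, 0.90000000000000002, 0.092999999999999999]
    },
    {
      "antecedent": ["B", "S", "S"],
      "theta": 1,
      "beliefs": [0.01, 0.28000000000000003, 0.63200000000000001, 0.078]
    },
    {
      "antecedent": ["B", "S", "N"],
      "theta": 1,
      "beliefs": [0.002, 0.121, 0.79600000000000004, 0.081000000000000003]
    },
    {
      "antecedent": ["B", "S", "H"],
      "theta": 1,
      "beliefs": [0.0060000000000000001, 0.012, 0.84299999999999997, 0.13900000000000001]
    },
    {
      "antecedent": ["B", "N", "S"],
      "theta": 1,
      "beliefs": [0.0040000000000000001, 0.052999999999999999, 0.69799999999999995, 0.245]
    },
    {
      "antecedent": ["B", "N", "N"],
      "theta": 1,
      "beliefs": [0.0030000000000000001, 0.027, 0.32500000000000001, 0.64500000000000002]
    },
    {
      "antecedent": ["B", "N", "H"],
      "theta": 1,
      "beliefs": [0.0030000000000000001, 0.064000000000000001, 0.182, 0.751]
    },
    {
      "antecedent": ["B", "L", "S"],
      "theta": 1,
      "beliefs": [0.0060000000000000001, 0.0089999999999999993, 0.311, 0.67400000000000004]
    },
    {
      "antecedent": ["B", "L", "N"],
      "theta": 1,
      "beliefs": [0.001, 0.0030000000000000001, 0.082000000000000003, 0.91400000000000003]
    },
    {
      "antecedent": ["B", "L", "H"],
      "theta": 1,
      "beliefs": [0.0070000000000000001, 0.021000000000000001, 0.035999999999999997, 0.93600000000000005]
    }
  ]
}
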