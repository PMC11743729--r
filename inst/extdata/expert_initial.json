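{
  "schema_version": 1,
  "note": "expert-elicited initial parameters",
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
      "beliefs": [1, 0, 0, 0]
    },
    {
      "antecedent": ["S", "S", "N"],
      "theta": 1,
      "beliefs": [0.90000000000000002, 0.10000000000000001, 0, 0]
    },
    {
      "antecedent": ["S", "S", "H"],
      "theta": 1,
      "beliefs": [0.80000000000000004, 0.20000000000000001, 0, 0]
    },
    {
      "antecedent": ["S", "N", "S"],
      "theta": 1,
      "beliefs": [0.90000000000000002, 0.10000000000000001, 0, 0]
    },
    {
      "antecedent": ["S", "N", "N"],
      "theta": 1,
      "beliefs": [0.80000000000000004, 0.20000000000000001, 0, 0]
    },
    {
      "antecedent": ["S", "N", "H"],
      "theta": 1,
      "beliefs": [0.69999999999999996, 0.29999999999999999, 0, 0]
    },
    {
      "antecedent": ["S", "L", "S"],
      "theta": 1,
      "beliefs": [0.59999999999999998, 0.29999999999999999, 0.10000000000000001, 0]
    },
    {
      "antecedent": ["S", "L", "N"],
      "theta": 1,
      "beliefs": [0.5, 0.40000000000000002, 0.10000000000000001, 0]
    },
    {
      "antecedent": ["S", "L", "H"],
      "theta": 1,
      "beliefs": [0, 0.90000000000000002, 0.10000000000000001, 0]
    },
    {
      "antecedent": ["N", "S", "S"],
      "theta": 1,
      "beliefs": [0.80000000000000004, 0.20000000000000001, 0, 0]
    },
    {
      "antecedent": ["N", "S", "N"],
      "theta": 1,
      "beliefs": [0.40000000000000002, 0.5, 0.10000000000000001, 0]
    },
    {
      "antecedent": ["N", "S", "H"],
      "theta": 1,
      "beliefs": [0.29999999999999999, 0.40000000000000002, 0.29999999999999999, 0]
    },
    {
      "antecedent": ["N", "N", "S"],
      "theta": 1,
      "beliefs": [0.20000000000000001, 0.59999999999999998, 0.20000000000000001, 0]
    },
    {
      "antecedent": ["N", "N", "N"],
      "theta": 1,
      "beliefs": [0.10000000000000001, 0.20000000000000001, 0.69999999999999996, 0]
    },
    {
      "antecedent": ["N", "N", "H"],
      "theta": 1,
      "beliefs": [0, 0.29999999999999999, 0.69999999999999996, 0]
    },
    {
      "antecedent": ["N", "L", "S"],
      "theta": 1,
      "beliefs": [0, 0.10000000000000001, 0.90000000000000002, 0]
    },
    {
      "antecedent": ["N", "L", "N"],
      "theta": 1,
      "beliefs": [0, 0, 1, 0]
    },
    {
      "antecedent": ["N", "L", "H"],
      "theta": 1,
      "beliefs": [0, 0, 0.90000000000000002, 0.10000000000000001]
    },
    {
      "antecedent": ["B", "S", "S"],
      "theta": 1,
      "beliefs": [0, 0.29999999999999999, 0.59999999999999998, 0.10000000000000001]
    },
    {
      "antecedent": ["B", "S", "N"],
      "theta": 1,
      "beliefs": [0, 0.20000000000000001, 0.69999999999999996, 0.10000000000000001]
    },
    {
      "antecedent": ["B", "S", "H"],
      "theta": 1,
      "beliefs": [0, 0.10000000000000001, 0.80000000000000004, 0.10000000000000001]
    },
    {
      "antecedent": ["B", "N", "S"],
      "theta": 1,
      "beliefs": [0, 0, 0.69999999999999996, 0.29999999999999999]
    },
    {
      "antecedent": ["B", "N", "N"],
      "theta": 1,
      "beliefs": [0, 0, 0.29999999999999999, 0.69999999999999996]
    },
    {
      "antecedent": ["B", "N", "H"],
      "theta": 1,
      "beliefs": [0, 0, 0.10000000000000001, 0.90000000000000002]
    },
    {
      "antecedent": ["B", "L", "S"],
      "theta": 1,
      "beliefs": [0, 0, 0.20000000000000001, 0.80000000000000004]
    },
    {
      "antecedent": ["B", "L", "N"],
      "theta": 1,
      "beliefs": [0, 0, 0.10000000000000001, 0.90000000000000002]
    },
    {
      "antecedent": ["B", "L", "H"],
      "theta": 1,
      "beliefs": [0, 0, 0, 1]
    }
  ]
}
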