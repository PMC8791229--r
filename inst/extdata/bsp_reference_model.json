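{
  "description": "Published nine-node LASSO-logistic reference model classifying blepharospasm patients vs healthy controls from nodal-efficiency (Enod) AUC features on a 160-node functional atlas, together with the reported group-mean feature values, decision cutoff and ROC summary.",
  "feature": "nodal efficiency AUC over sparsity 0.10-0.34",
  "intercept": -12.582335,
  "cutoff": 0.5307,
  "reported_roc": {
    "auc": 0.995,
    "ci_low": 0.973,
    "ci_high": 1.0,
    "sensitivity": 0.95,
    "specificity": 1.0
  },
  "nodes": [
    {"node_id": 21, "region": "Precuneus", "hemisphere": "R", "network": "Default", "coefficient": 25.6232737, "patient_mean": 0.1371, "patient_sd": 0.0010, "control_mean": 0.1284, "control_sd": 0.0088, "p_value": 0.0132, "q_value": 0.0341},
    {"node_id": 30, "region": "IPS", "hemisphere": "L", "network": "Default", "coefficient": 9.10143256, "patient_mean": 0.1382, "patient_sd": 0.0087, "control_mean": 0.1317, "control_sd": 0.0073, "p_value": 0.0181, "q_value": 0.0341},
    {"node_id": 117, "region": "Post parietal/postcentral", "hemisphere": "L", "network": "Sensorimotor", "coefficient": 41.1562545, "patient_mean": 0.1433, "patient_sd": 0.0068, "control_mean": 0.1354, "control_sd": 0.0110, "p_value": 0.0227, "q_value": 0.0341},
    {"node_id": 126, "region": "Occipital", "hemisphere": "R", "network": "Occipital", "coefficient": 10.2355905, "patient_mean": 0.1397, "patient_sd": 0.0063, "control_mean": 0.1352, "control_sd": 0.0073, "p_value": 0.0195, "q_value": 0.0341},
    {"node_id": 143, "region": "Lat cerebellum", "hemisphere": "L", "network": "Cerebellum", "coefficient": 17.2030057, "patient_mean": 0.1349, "patient_sd": 0.0083, "control_mean": 0.1302, "control_sd": 0.0070, "p_value": 0.0810, "q_value": 0.0911},
    {"node_id": 150, "region": "Med cerebellum", "hemisphere": "L", "network": "Cerebellum", "coefficient": 36.1654607, "patient_mean": 0.1441, "patient_sd": 0.0090, "control_mean": 0.1366, "control_sd": 0.0086, "p_value": 0.0095, "q_value": 0.0341},
    {"node_id": 42, "region": "dlPFC", "hemisphere": "R", "network": "Fronto-parietal", "coefficient": -4.0251895, "patient_mean": 0.1349, "patient_sd": 0.0081, "control_mean": 0.1386, "control_sd": 0.0100, "p_value": 0.2315, "q_value": 0.2315},
    {"node_id": 62, "region": "Ant insula", "hemisphere": "L", "network": "Cingulo-opercular", "coefficient": -2.7689898, "patient_mean": 0.1440, "patient_sd": 0.0010, "control_mean": 0.1502, "control_sd": 0.0069, "p_value": 0.0375, "q_value": 0.0482},
    {"node_id": 98, "region": "Parietal/precentral", "hemisphere": "L", "network": "Sensorimotor", "coefficient": -39.31437, "patient_mean": 0.1389, "patient_sd": 0.0094, "control_mean": 0.1455, "control_sd": 0.0048, "p_value": 0.0039, "q_value": 0.0341}
  ]
}
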