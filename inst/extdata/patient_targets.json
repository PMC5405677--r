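[
  {
    "index": "aoroot_pressure_mean",
    "value": 56.4,
    "rule": "rel",
    "tol": 10,
    "lower": null,
    "upper": null
  },
  {
    "index": "aoroot_pressure_systolic",
    "value": null,
    "rule": "none",
    "tol": 10,
    "lower": null,
    "upper": null
  },
  {
    "index": "aoroot_pressure_diastolic",
    "value": null,
    "rule": "none",
    "tol": 10,
    "lower": null,
    "upper": null
  },
  {
    "index": "aoroot_pressure_pulse",
    "value": null,
    "rule": "none",
    "tol": 10,
    "lower": null,
    "upper": null
  },
  {
    "index": "LPA_pressure_mean",
    "value": 16.5,
    "rule": "range",
    "tol": 10,
    "lower": 12.9,
    "upper": 16.5
  },
  {
    "index": "RPA_pressure_mean",
    "value": 12.9,
    "rule": "range",
    "tol": 10,
    "lower": 12.9,
    "upper": 16.5
  },
  {
    "index": "aoroot_flow_mean",
    "value": null,
    "rule": "none",
    "tol": 10,
    "lower": null,
    "upper": null
  },
  {
    "index": "DAo_flow_mean",
    "value": null,
    "rule": "none",
    "tol": 10,
    "lower": null,
    "upper": null
  },
  {
    "index": "SVC_flow_mean",
    "value": null,
    "rule": "none",
    "tol": 10,
    "lower": null,
    "upper": null
  },
  {
    "index": "IVC_flow_mean",
    "value": null,
    "rule": "none",
    "tol": 10,
    "lower": null,
    "upper": null
  },
  {
    "index": "LPA_flow_mean",
    "value": null,
    "rule": "none",
    "tol": 10,
    "lower": null,
    "upper": null
  },
  {
    "index": "RPA_flow_mean",
    "value": null,
    "rule": "none",
    "tol": 10,
    "lower": null,
    "upper": null
  },
  {
    "index": "LPV_flow_mean",
    "value": null,
    "rule": "none",
    "tol": 10,
    "lower": null,
    "upper": null
  },
  {
    "index": "RPV_flow_mean",
    "value": null,
    "rule": "none",
    "tol": 10,
    "lower": null,
    "upper": null
  },
  {
    "index": "ASD_flow_mean",
    "value": null,
    "rule": "none",
    "tol": 10,
    "lower": null,
    "upper": null
  },
  {
    "index": "shunt_flow_mean",
    "value": 9.7,
    "rule": "rel",
    "tol": 10,
    "lower": null,
    "upper": null
  }
]
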