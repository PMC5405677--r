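{
  "model": "baseline",
  "dt": 0.0001,
  "period": 0.46,
  "max_cycles": 60,
  "tol": 0.001,
  "P0": 10,
  "seed": null,
  "tables": {
    "windkessel_outlets": {
      "RC": {
        "Rp": 0.50931,
        "Rd": 2.68885,
        "C": 0.71603
      },
      "LC": {
        "Rp": 0.50004,
        "Rd": 2.43319,
        "C": 0.74383
      },
      "RS": {
        "Rp": 0.50878,
        "Rd": 2.6307,
        "C": 0.74512
      },
      "LS": {
        "Rp": 0.45264,
        "Rd": 2.10615,
        "C": 0.84197
      },
      "DAo": {
        "Rp": 0.05919,
        "Rd": 0.28437,
        "C": 5.01933
      },
      "RPA": {
        "Rp": 0.03277,
        "Rd": 0.1361,
        "C": 1.76235
      },
      "LPA": {
        "Rp": 0.03108,
        "Rd": 0.3195,
        "C": 1.00099
      }
    },
    "venous_sections": {
      "SVC": {
        "Rp": 0.155,
        "Rd": 0.01807,
        "C": 284.73779
      },
      "IVC": {
        "Rp": 0.22075,
        "Rd": 0.02261,
        "C": 135.9563
      },
      "RPV": {
        "Rp": 0.02693,
        "Rd": 0.0204,
        "C": 72.0547
      },
      "LPV": {
        "Rp": 0.01027,
        "Rd": 0.00897,
        "C": 132.9673
      }
    },
    "heart_and_shunts": {
      "RA_valve_R": 0.0033,
      "RA_valve_L": 6.667e-05,
      "NAV_R": 0.001,
      "NAV_L": 1e-05,
      "Collateral1": 0.09696,
      "Collateral2": 0.05,
      "ASD": 0.0003
    }
  },
  "surrogate": {
    "branch_R": {
      "RC": 0.001,
      "LC": 0.001,
      "RS": 0.001,
      "LS": 0.001,
      "DAo": 0.001
    },
    "pa_branch_R": {
      "LPA": 0.001,
      "RPA": 0.001
    },
    "shunt_mode": "empirical",
    "shunt_R": 3.5,
    "shunt_diameter_mm": 3.5,
    "shunt_length_mm": 14,
    "scale": 1,
    "viscosity_Pa_s": 0.004,
    "density_g_mm3": 0.00106
  },
  "heart": {
    "elastance": {
      "E_min": 0.2,
      "E_max": 3,
      "t0": 0.15,
      "sigma": 0.05,
      "period": 0.46
    },
    "V0": 5,
    "EDV": 40,
    "C_RA": 1,
    "C_LA": 1,
    "period": 0.46
  },
  "collateral1_nodes": null,
  "collateral2_nodes": null
}
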