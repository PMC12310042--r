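{
  "units": {
    "trafficking": "s^-1 (kprod: #/cell/s)",
    "kon_M": "M^-1 s^-1",
    "koff": "s^-1",
    "kon_rr_um2": "(#/um^2)^-1 s^-1",
    "koff_rr": "s^-1",
    "area": "um^2/cell",
    "volume_fl": "fL/cell",
    "rtot": "#/cell"
  },
  "geometry": {
    "area": {
      "surface": 1000,
      "rab4": 168.75,
      "rab11": 56.25
    },
    "volume_fl": {
      "surface": 10000000,
      "rab4": 11.25,
      "rab11": 3.75
    },
    "media_ml": 1,
    "cells_per_well": 100000
  },
  "rtot": {
    "R1": 1800,
    "R2": 4900,
    "N1": 68000
  },
  "trafficking": [
    {
      "receptor": "R1",
      "kint": 0.0035,
      "kdeg": 0.0004,
      "krec4": 5e-05,
      "k4to11": 6e-05,
      "krec11": 0.0003,
      "kprod": 4.94117647058823
    },
    {
      "receptor": "R2",
      "kint": 0.0002,
      "kdeg": 0.0002,
      "krec4": 1e-05,
      "k4to11": 1e-06,
      "krec11": 1e-05,
      "kprod": 0.928909952606635
    },
    {
      "receptor": "N1",
      "kint": 0.0005,
      "kdeg": 0.00025,
      "krec4": 0.0004,
      "k4to11": 0.00015,
      "krec11": 0.001,
      "kprod": 10.625
    }
  ],
  "ligated_multipliers": [
    {
      "receptor": "R1",
      "param": "kint",
      "multiplier": 1
    },
    {
      "receptor": "R1",
      "param": "kdeg",
      "multiplier": 1
    },
    {
      "receptor": "R1",
      "param": "krec4",
      "multiplier": 1
    },
    {
      "receptor": "R1",
      "param": "k4to11",
      "multiplier": 1
    },
    {
      "receptor": "R1",
      "param": "krec11",
      "multiplier": 1
    },
    {
      "receptor": "R2",
      "param": "kint",
      "multiplier": 3
    },
    {
      "receptor": "R2",
      "param": "kdeg",
      "multiplier": 1
    },
    {
      "receptor": "R2",
      "param": "krec4",
      "multiplier": 1
    },
    {
      "receptor": "R2",
      "param": "k4to11",
      "multiplier": 1
    },
    {
      "receptor": "R2",
      "param": "krec11",
      "multiplier": 1
    },
    {
      "receptor": "N1",
      "param": "kint",
      "multiplier": 1
    },
    {
      "receptor": "N1",
      "param": "kdeg",
      "multiplier": 1
    },
    {
      "receptor": "N1",
      "param": "krec4",
      "multiplier": 1
    },
    {
      "receptor": "N1",
      "param": "k4to11",
      "multiplier": 1
    },
    {
      "receptor": "N1",
      "param": "krec11",
      "multiplier": 1
    }
  ],
  "binding_1to1": [
    {
      "ligand": "V165",
      "partner": "R1",
      "kon_M": 30000000,
      "koff": 0.001
    },
    {
      "ligand": "V165",
      "partner": "R2",
      "kon_M": 10000000,
      "koff": 0.001
    },
    {
      "ligand": "V165",
      "partner": "N1",
      "kon_M": 3200000,
      "koff": 0.001
    },
    {
      "ligand": "V121",
      "partner": "R1",
      "kon_M": 30000000,
      "koff": 0.001
    },
    {
      "ligand": "V121",
      "partner": "R2",
      "kon_M": 10000000,
      "koff": 0.001
    },
    {
      "ligand": "P1",
      "partner": "R1",
      "kon_M": 6000000,
      "koff": 0.001
    },
    {
      "ligand": "P2",
      "partner": "R1",
      "kon_M": 6000000,
      "koff": 0.001
    },
    {
      "ligand": "P2",
      "partner": "N1",
      "kon_M": 3200000,
      "koff": 0.001
    },
    {
      "ligand": "V165",
      "partner": "M",
      "kon_M": 1000000,
      "koff": 0.01
    },
    {
      "ligand": "P2",
      "partner": "M",
      "kon_M": 1000000,
      "koff": 0.01
    }
  ],
  "coupling_rr": [
    {
      "pair": "R1-R1",
      "kon_rr_um2": 0.0062,
      "koff_rr": 0.01
    },
    {
      "pair": "R2-R2",
      "kon_rr_um2": 0.0023,
      "koff_rr": 0.01
    },
    {
      "pair": "N1-R1",
      "kon_rr_um2": 0.00012,
      "koff_rr": 0.01
    }
  ],
  "kdeg_ligand": 0.001,
  "compartment_rate_multipliers": [
    {
      "compartment": "surface",
      "kon_mult": 1,
      "koff_mult": 1
    },
    {
      "compartment": "rab4",
      "kon_mult": 1,
      "koff_mult": 1
    },
    {
      "compartment": "rab11",
      "kon_mult": 1,
      "koff_mult": 1
    }
  ]
}
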