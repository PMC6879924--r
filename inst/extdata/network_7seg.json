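{
  "units": {
    "length": "m",
    "radius": "m",
    "stiffness": "Pa (k1,k3), 1/m (k2)",
    "wall_viscosity": "g/s (b0), g.cm/s (b1)",
    "resistance": "Pa.s.m-3",
    "compliance": "m3.Pa-1",
    "pressure": "Pa"
  },
  "inlet": "aorta_prox",
  "segments": [
    {
      "id": "aorta_prox",
      "length": 0.08,
      "r_in": 0.018,
      "r_out": 0.0135,
      "k1": 200000,
      "k2": -100,
      "k3": 60000,
      "b0": 600,
      "b1": 150
    },
    {
      "id": "aorta_dist",
      "length": 0.3,
      "r_in": 0.013,
      "r_out": 0.008,
      "k1": 200000,
      "k2": -100,
      "k3": 60000,
      "b0": 600,
      "b1": 150
    },
    {
      "id": "carotid",
      "length": 0.18,
      "r_in": 0.0031,
      "r_out": 0.0031,
      "k1": 200000,
      "k2": -100,
      "k3": 60000,
      "b0": 600,
      "b1": 150
    },
    {
      "id": "arm",
      "length": 0.6,
      "r_in": 0.004,
      "r_out": 0.0016,
      "k1": 200000,
      "k2": -100,
      "k3": 60000,
      "b0": 600,
      "b1": 150
    },
    {
      "id": "iliac",
      "length": 0.06,
      "r_in": 0.007,
      "r_out": 0.0065,
      "k1": 200000,
      "k2": -100,
      "k3": 60000,
      "b0": 600,
      "b1": 150
    },
    {
      "id": "leg_a",
      "length": 0.7,
      "r_in": 0.005,
      "r_out": 0.0022,
      "k1": 200000,
      "k2": -100,
      "k3": 60000,
      "b0": 600,
      "b1": 150
    },
    {
      "id": "leg_b",
      "length": 0.7,
      "r_in": 0.005,
      "r_out": 0.0022,
      "k1": 200000,
      "k2": -100,
      "k3": 60000,
      "b0": 600,
      "b1": 150
    }
  ],
  "junctions": [
    {
      "parent": "aorta_prox",
      "daughters": ["aorta_dist", "carotid"]
    },
    {
      "parent": "aorta_dist",
      "daughters": ["arm", "iliac"]
    },
    {
      "parent": "iliac",
      "daughters": ["leg_a", "leg_b"]
    }
  ],
  "outlets": [
    {
      "segment": "carotid",
      "bed": "head",
      "bed_fraction": 0.25,
      "R1": 500000000,
      "R2": 1500000000,
      "C": 8e-10,
      "P_out": 0
    },
    {
      "segment": "arm",
      "bed": "arm",
      "bed_fraction": 0.15,
      "R1": 1200000000,
      "R2": 4000000000,
      "C": 3e-10,
      "P_out": 0
    },
    {
      "segment": "leg_a",
      "bed": "leg",
      "bed_fraction": 0.6,
      "R1": 400000000,
      "R2": 1200000000,
      "C": 1.2e-09,
      "P_out": 0
    },
    {
      "segment": "leg_b",
      "bed": "leg",
      "bed_fraction": 0.6,
      "R1": 400000000,
      "R2": 1200000000,
      "C": 1.2e-09,
      "P_out": 0
    }
  ],
  "sites": [
    {
      "site": "aortic_root",
      "segment": "aorta_prox",
      "fraction": 0
    },
    {
      "site": "carotid",
      "segment": "carotid",
      "fraction": 0.5
    },
    {
      "site": "wrist",
      "segment": "arm",
      "fraction": 0.95,
      "ppg": "windkessel"
    },
    {
      "site": "ankle_a",
      "segment": "leg_a",
      "fraction": 0.95,
      "ppg": "windkessel"
    }
  ],
  "blood": {
    "density": 1060,
    "viscosity": 0.0025
  }
}
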