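{
  "model": {
    "g0": 1.09,
    "induction": {
      "z_basal": 0.00574203409184681,
      "z_max": 1,
      "k_half": 13.2746629696065,
      "hill_n": 1.62736171671829,
      "k_anti": 1000
    },
    "cost": {
      "eta0": 0.138716039677331,
      "m_sat": 3.2182540213578,
      "form": "saturating"
    },
    "benefit": {
      "delta": 2.12411810472258,
      "k_pgal": 362.026417850282,
      "hill_p": 2.06466701778861,
      "z_exponent": 0.290063106003849
    }
  },
  "noise_cv": 0.043,
  "residuals": [
    {
      "anchor": "g0",
      "target": 1.09,
      "achieved": 1.09,
      "rel_residual": 0
    },
    {
      "anchor": "full_induction_cost",
      "target": 0.2,
      "achieved": 0.200094339764996,
      "rel_residual": 0.000471698824981992
    },
    {
      "anchor": "balance_pgal",
      "target": 120,
      "achieved": 120.039299857077,
      "rel_residual": 0.00032749880897569
    },
    {
      "anchor": "max_net_increase",
      "target": 1.6,
      "achieved": 1.59829135537052,
      "rel_residual": -0.00106790289342629
    },
    {
      "anchor": "i_opt_100",
      "target": 5,
      "achieved": 5.00197580346918,
      "rel_residual": 0.000395160693835273
    },
    {
      "anchor": "i_opt_240",
      "target": 30,
      "achieved": 30.0115599528552,
      "rel_residual": 0.00038533176183897
    },
    {
      "anchor": "zopt_inflection",
      "target": 150,
      "achieved": 150.24797360306,
      "rel_residual": 0.00165315735373137
    }
  ]
}
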