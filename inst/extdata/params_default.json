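{
  "exam_rate": {"base": 0.42, "low": 0.315, "high": 0.525},

  "prev_t2dm_lt40": {"base": 0.0456, "low": 0.0415, "high": 0.0497},
  "prev_t2dm_40_60": {"base": 0.0822, "low": 0.0790, "high": 0.0854},
  "prev_t2dm_gt60": {"base": 0.1250, "low": 0.1184, "high": 0.1316},

  "prev_iifg_lt40": {"base": 0.1728, "low": 0.1296, "high": 0.2160},
  "prev_iifg_40_60": {"base": 0.1018, "low": 0.0764, "high": 0.1273},
  "prev_iifg_gt60": {"base": 0.1394, "low": 0.1045, "high": 0.1742},

  "prev_iigt_lt40": {"base": 0.0821, "low": 0.0616, "high": 0.1026},
  "prev_iigt_40_60": {"base": 0.2051, "low": 0.1538, "high": 0.2564},
  "prev_iigt_gt60": {"base": 0.2259, "low": 0.1694, "high": 0.2823},

  "prev_ifgigt_lt40": {"base": 0.0372, "low": 0.0279, "high": 0.0464},
  "prev_ifgigt_40_60": {"base": 0.1093, "low": 0.0820, "high": 0.1366},
  "prev_ifgigt_gt60": {"base": 0.1370, "low": 0.1027, "high": 0.1712},

  "fpg_sens_t2dm": {"base": 0.7342, "low": 0.5506, "high": 0.9177},
  "fpg_sens_iifg": {"base": 0.4609, "low": 0.3457, "high": 0.5761},
  "fpg_sens_iigt": {"base": 0.0, "low": 0.0, "high": 0.0},
  "fpg_sens_ifgigt": {"base": 0.6974, "low": 0.5231, "high": 0.8718},
  "fpg_fp_ngt": {"base": 0.10, "low": 0.075, "high": 0.125},
  "cdrs_sens_t2dm": {"base": 0.876, "low": 0.657, "high": 1.0},
  "cdrs_sens_prediab": {"base": 0.7339, "low": 0.5504, "high": 0.9173},
  "cdrs_fp_ngt": {"base": 0.4474, "low": 0.3355, "high": 0.5592},

  "trans_ngt_iifg": {"base": 0.0204, "low": 0.0153, "high": 0.0255},
  "trans_ngt_iigt": {"base": 0.0646, "low": 0.0485, "high": 0.0808},
  "trans_ngt_ifgigt": {"base": 0.0276, "low": 0.0207, "high": 0.0345},

  "trans_iifg_t2dm_undiag_lt40": {"base": 0.0779, "low": 0.0584, "high": 0.0974},
  "trans_iifg_t2dm_undiag_40_50": {"base": 0.0290, "low": 0.0248, "high": 0.0492},
  "trans_iifg_t2dm_undiag_50_60": {"base": 0.0298, "low": 0.0135, "high": 0.0298},
  "trans_iifg_t2dm_undiag_gt60": {"base": 0.0359, "low": 0.0269, "high": 0.0449},

  "trans_iifg_t2dm_diag_lt40": {"base": 0.0911, "low": 0.0390, "high": 0.2134},
  "trans_iifg_t2dm_diag_40_50": {"base": 0.0339, "low": 0.0145, "high": 0.0793},
  "trans_iifg_t2dm_diag_50_60": {"base": 0.0349, "low": 0.0149, "high": 0.0817},
  "trans_iifg_t2dm_diag_gt60": {"base": 0.0420, "low": 0.0180, "high": 0.0984},

  "trans_iigt_t2dm_undiag_lt40": {"base": 0.1091, "low": 0.0818, "high": 0.1364},
  "trans_iigt_t2dm_undiag_40_50": {"base": 0.0638, "low": 0.0546, "high": 0.1084},
  "trans_iigt_t2dm_undiag_50_60": {"base": 0.0657, "low": 0.0447, "high": 0.0909},
  "trans_iigt_t2dm_undiag_gt60": {"base": 0.0791, "low": 0.0593, "high": 0.0989},

  "trans_iigt_t2dm_diag_lt40": {"base": 0.0589, "low": 0.0393, "high": 0.0884},
  "trans_iigt_t2dm_diag_40_50": {"base": 0.0344, "low": 0.0230, "high": 0.0517},
  "trans_iigt_t2dm_diag_50_60": {"base": 0.0355, "low": 0.0237, "high": 0.0532},
  "trans_iigt_t2dm_diag_gt60": {"base": 0.0427, "low": 0.0285, "high": 0.0641},

  "trans_ifgigt_t2dm_undiag_lt40": {"base": 0.0854, "low": 0.0641, "high": 0.1068},
  "trans_ifgigt_t2dm_undiag_40_50": {"base": 0.1111, "low": 0.0905, "high": 0.1888},
  "trans_ifgigt_t2dm_undiag_50_60": {"base": 0.1145, "low": 0.0779, "high": 0.1584},
  "trans_ifgigt_t2dm_undiag_gt60": {"base": 0.1378, "low": 0.1034, "high": 0.1723},

  "trans_ifgigt_t2dm_diag_lt40": {"base": 0.0427, "low": 0.0307, "high": 0.0589},
  "trans_ifgigt_t2dm_diag_40_50": {"base": 0.0556, "low": 0.0400, "high": 0.0767},
  "trans_ifgigt_t2dm_diag_50_60": {"base": 0.0572, "low": 0.0412, "high": 0.0790},
  "trans_ifgigt_t2dm_diag_gt60": {"base": 0.0689, "low": 0.0496, "high": 0.0951},

  "trans_iifg_ngt": {"base": 0.0689, "low": 0.0516, "high": 0.0861},
  "trans_iigt_ngt": {"base": 0.0883, "low": 0.0662, "high": 0.1103},
  "trans_ifgigt_ngt": {"base": 0.0534, "low": 0.0401, "high": 0.0668},

  "fpg_cost": {"base": 5.49, "low": 3.64, "high": 7.97},
  "ogtt_cost": {"base": 13.36, "low": 11.62, "high": 15.82},
  "intervention_cost": {"base": 26.66, "low": 22.06, "high": 31.98},
  "cdrs_cost": {"base": 0.0, "low": 0.0, "high": 0.0},
  "interventions_per_year": {"base": 2, "low": 2, "high": 2},

  "discount_rate": {"base": 0.05, "low": 0.0, "high": 0.08},
  "wtp": {"base": 12551, "low": 12551, "high": 12551},
  "compliance": {"base": 1.0, "low": 0.01, "high": 1.0}
}
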