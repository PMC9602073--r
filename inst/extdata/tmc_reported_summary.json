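{
  "comment": "Published pedigree/genomic diversity summary statistics for the Tropical Milking Criollo cattle population (reported values; the underlying raw data are confidential).",
  "total_population": {
    "n_pedigree": 3780, "fped_pct": 1.73, "pct_inbred": 37.3,
    "fped_inbred_pct": 4.62, "ar_pct": 2.75, "eqg": 3.0, "maxg": 7.3,
    "fe": 78, "fa": 48, "n_half": 19, "fa_fe_ratio": 0.61
  },
  "reference_population": {
    "n_genotyped": 79, "fped_pct": 2.82, "pct_inbred": 86.84,
    "fped_inbred_pct": 3.25, "ar_pct": 4.67, "eqg": 5.01, "maxg": 10.4,
    "fe": 45, "fa": 24, "n_half": 9, "fa_fe_ratio": 0.53
  },
  "ne": 94.24, "mean_delta_f_pct": 0.53,
  "generation_interval_total": {"n": 2154, "mean_years": 6.97, "se_years": 0.09},
  "genomic": {"fgrm_pct_mean": -0.7, "fgrm_pct_sd": 3.8,
              "froh_pct_mean": 10.9, "froh_pct_sd": 3.0,
              "n_roh_total": 9512, "pct_roh_1_2mb": 76}
}
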