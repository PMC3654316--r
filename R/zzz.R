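.datatable.aware <- TRUE

# data.table NSE columns
utils::globalVariables(c(
  ".", "h", "k", "l", "intensity", "sigma", "image", "dataset_id",
  "bin", "key", "n_h", "ibar", "dev", "isum", "w", "iw", "d", "sign",
  "mean_i", "mean_d", "s2", "expected", "z_score", "reason",
  "i_merged", "correlation", "candidate", "n_common",
  "ch", "ck", "cl", "i_1", "i_-1", "s_1", "s_-1", "fp", "fm", "sp", "sm",
  "danom", "sdanom", "hand", "solvent_fraction", "shell",
  "mean_i_over_sigma_merged", "n_rotations", "r_meas", "symbol", "u",
  "i_true", "tied"))
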