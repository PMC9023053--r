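#' @import data.table
#' @keywords internal
"_PACKAGE"

# data.table NSE column names used across the package.
utils::globalVariables(c(
  ".", ".I", ".N", ".SD", "antigen", "ball_pgen", "ball_se", "batch",
  "bucket", "called", "cdr3aa", "cdr3nt", "cluster_id", "comp", "count",
  "d", "d_obs", "db_cdr3aa", "freq", "go", "hit", "hla", "hla_pass",
  "i.row", "id", "idx", "is_hit", "j", "key", "lambda", "lambda_se",
  "len", "log2fc", "masked", "mean_focal", "mean_ref", "n", "n_exact",
  "N_vj", "p_value", "point_pgen", "pos", "prob", "productive",
  "q_value", "qidx", "res", "role", "row_id", "sample", "specificity",
  "v", "vtrim", "weight", "x.row"))
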