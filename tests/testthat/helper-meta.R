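# hand-built study tables used across the meta-analysis tests

toy_studies <- function(case_null, case_present, control_null,
                        control_present, ids = NULL) {
  k <- length(case_null)
  as_genotype_studies(data.frame(
    study_id = ids %||% sprintf("s%02d", seq_len(k)),
    ethnicity = "test",
    case_null = case_null, case_present = case_present,
    control_null = control_null, control_present = control_present,
    stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a table whose genotype distribution is exactly independent (OR = 1)
null_study <- function(scale = 1) {
  c(case_null = 20, case_present = 10, control_null = 40,
    control_present = 20) * scale
}
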