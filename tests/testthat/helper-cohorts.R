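# Shared fixtures built in code.

# minimal valid cohort data frame with overridable fields
toy_cohort <- function(n = 3, ...) {
  base <- data.frame(
    patient_id = sprintf("p%02d", seq_len(n)),
    sex = rep_len(c("male", "female"), n),
    age = rep(65, n),
    smoking = rep("any", n),
    ecog = rep(1, n),
    histology = rep("non_squamous", n),
    egfr_alk = rep("no", n),
    nlr1 = rep(4, n),
    nlr2 = rep(4.2, n),
    pdl1 = rep("unknown", n),
    prior_lines = rep(1, n),
    treatment = rep("pd1_mono", n),
    line_setting = rep("post_platinum", n),
    cohort = rep("training", n),
    os_time = seq_len(n) + 1,
    os_event = rep(1, n),
    pfs_time = seq_len(n),
    pfs_event = rep(1, n),
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}

write_toy_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "NA")
  path
}

# exponential survival sample with uniform censoring
sim_exp_censored <- function(n, median_months, cens_range = c(12, 36)) {
  t_event <- stats::rexp(n, log(2) / median_months)
  t_cens <- stats::runif(n, cens_range[1], cens_range[2])
  list(time = pmin(t_event, t_cens),
       event = as.integer(t_event <= t_cens))
}
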