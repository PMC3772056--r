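#!/usr/bin/env Rscript
# Simulate the behavioural study: 18 subjects, 324 comparison + 324
# sequential trials each, choices from heterogeneous prospect-theory agents
# with a slight bias toward the second-presented option on sequential trials.
# Writes one TSV per subject plus the generating parameters.

library(valueframes)

out_dir <- "results/sessions"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

seed <- 20260901
n_subjects <- 18
params <- draw_subject_params(n_subjects, seed = seed)

truth <- data.frame(subject = seq_len(n_subjects),
                    alpha = vapply(params, `[[`, 0, "alpha"),
                    gamma = vapply(params, `[[`, 0, "gamma"),
                    beta = vapply(params, `[[`, 0, "beta"))
write.csv(truth, file.path("results", "generating_parameters.csv"),
          row.names = FALSE)

for (s in seq_len(n_subjects)) {
  tr <- simulate_session(params[[s]], n_per_type = 324, order_bias = 0.5,
                         seed = seed + s)
  write_trials_tsv(tr, file.path(out_dir, sprintf("subject%02d.tsv", s)))
}

cat(sprintf("wrote %d sessions (%d trials each) to %s\n",
            n_subjects, 648, out_dir))
cat(sprintf("nobrainer proportion across cohort: %.3f\n",
            mean(vapply(seq_len(n_subjects), function(s)
              mean(read_trials_tsv(
                file.path(out_dir, sprintf("subject%02d.tsv", s)))$nobrainer),
              0))))
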