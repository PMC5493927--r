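#!/usr/bin/env Rscript
# H4: age-at-death profile (10-year bins, interval-apportioned) and the
# sex-parity chi-square test on the burial table.

suppressPackageStartupMessages(library(paleopuna))
dir.create("results", showWarnings = FALSE)

burials <- smp_burials()
profile <- build_profile(burials, bin_width = 10)
print(profile)
print(profile$age_histogram)

parity <- sex_parity_chisq(profile$sex_counts[["f"]],
                           profile$sex_counts[["m"]])
cat(sprintf("sex parity: chi2(1) = %.2f, p = %.2f\n",
            parity$chi2, parity$p))

write_profile(profile, "results/age_profile.csv",
              "results/demography_report.json")

support <- evaluate_demography(profile)
cat("\nper-model demographic support:\n")
print(as.data.frame(support))
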