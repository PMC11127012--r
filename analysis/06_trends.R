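#!/usr/bin/env Rscript
# Stage 6 -- long-term trend statistics on the completed chlorophyll series.
#
# Annual aggregates (cumulative, mean, CV, max, min) are computed on the
# ensemble-mean series; the first vs last complete decades are compared by
# Welch t-tests; annual maxima/minima get log-linear fits; and the decadal
# weekly climatologies are compared pairwise with the k-sample
# Anderson-Darling test.

library(baybloom)

ens_df <- read.csv("results/analysis/ensemble.csv")
vals <- rowMeans(as.matrix(ens_df[, grep("^m", names(ens_df)), drop = FALSE]))
series <- weekly_series(vals, ens_df$year[1], ens_df$week[1], name = "chl",
                        unit = "mg chl m-3")

summ <- annual_summaries(series)
write.csv(summ, "results/analysis/annual_summaries.csv", row.names = FALSE)

first <- decade_spec("first", 1973, 1982)
last <- decade_spec("last", 2009, 2019)
tests <- lapply(c(cumulative = "cumulative", max = "max", cv = "cv"),
                function(f) decade_compare(summ, first, last, f))
write.csv(do.call(rbind, lapply(names(tests), function(f) {
  d <- tests[[f]]
  data.frame(field = f, t = d$t, df = d$df, p = d$p,
             percent_change = d$percent_change)
})), "results/analysis/decade_tests.csv", row.names = FALSE)

message(sprintf("cumulative annual chl: %.0f%% change first->last decade (t = %.2f, p = %.2g)",
                tests$cumulative$percent_change, tests$cumulative$t,
                tests$cumulative$p))
message(sprintf("bloom intensity (annual max): %.0f%% change (t = %.2f, p = %.2g)",
                tests$max$percent_change, tests$max$t, tests$max$p))
message(sprintf("annual CV: %.0f%% -> %.0f%% (p = %.2f); series mean CV %.0f%%",
                tests$cv$mean_first, tests$cv$mean_last, tests$cv$p,
                mean(summ$cv)))

fits <- list(max = loglinear_trend(summ$max, summ$year),
             min = loglinear_trend(summ$min, summ$year))
write.csv(do.call(rbind, lapply(names(fits), function(f) {
  d <- fits[[f]]
  data.frame(field = f, slope = d$slope, intercept = d$intercept,
             r_squared = d$r_squared, p = d$p)
})), "results/analysis/trend_fits.csv", row.names = FALSE)
message(sprintf("log annual max trend: slope %.3f /yr (R2 = %.2f, p = %.2g)",
                fits$max$slope, fits$max$r_squared, fits$max$p))

decades <- list(decade_spec("1970s", 1970, 1979), decade_spec("1980s", 1980, 1989),
                decade_spec("1990s", 1990, 1999), decade_spec("2000s", 2000, 2009),
                decade_spec("2010s", 2010, 2019))
clim <- decadal_climatology(series, decades)
write.csv(cbind(week = 1:52, as.data.frame(clim)),
          "results/analysis/climatology.csv", row.names = FALSE)

ad <- pairwise_decade_tests(series, decades, method = "asymptotic")
write.csv(as.data.frame(ad$p), "results/analysis/ad_matrix.csv")
off <- ad$p[upper.tri(ad$p)]
message(sprintf("pairwise decadal AD tests: %d of %d pairs differ at p<0.001",
                sum(off < 0.001), length(off)))
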