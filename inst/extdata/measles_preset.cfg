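# Preset for fitting historical measles case-report series (user supplies
# the file; time unit = years). The raw reports are sparse in time, so the
# series is cubic-spline resampled before embedding.
# input = measles.csv
# column = cases
# dt = <reporting interval in years, e.g. 0.0192 for biweekly>
resample_dt = 0.0018
m = 51
r = 6
variant = shavok
centred = true
closed = false
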