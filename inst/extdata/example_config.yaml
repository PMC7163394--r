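# Example pipeline configuration. Unset fields fall back to the package
# defaults (see default_run_config()): 35 goats, 4 periods x 4 days,
# 2-min sampling over 22 h, 5-g scale, 900-min analysis window, 8 slope
# clusters, 30-min minimum pause, 0.95 repeatability threshold.
seed: 1
missing: pattern        # none | pattern | (data.frame when configured in R)
design:
  n_goats: 35
  n_periods: 4
  n_days: 4
  interval: 2           # min
  window: 1320          # min (22 h)
  resolution: 5         # g as-fed
day_window: 900         # min (15 h analysis window)
k_clusters: 8
min_pause: 30           # min
repeatability_threshold: 0.95
# To analyse recorded data instead of a simulation, point `inputs` at CSVs:
# inputs:
#   trough: path/to/trough.csv
#   bw: path/to/bw.csv
#   feed: path/to/feed.csv
#   refusal: path/to/refusal.csv
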