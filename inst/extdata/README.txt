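Small plain-text inputs shipped with condemnr.

published_cause_counts.csv
  Whole-period (Jan 2009 - Nov 2019) condemnation counts per cause, as
  published in aggregate form for a Brazilian federal-inspection export
  slaughterhouse series. Used to reproduce the percent-share accounting.

published_group_means.csv
  Published per-group summary statistics (percent condemnation per month,
  groups A = turkey + chicken months, B = heavy-chicken-only months) for the
  same series: n, mean, SD, SE and rank-biserial correlation per variable.

exclusions_example.yaml
  Example exclusion config listing the two months removed from that series
  for data inconsistencies.
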