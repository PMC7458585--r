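Bundled example tables
======================

table1_google_apc.csv / table2_google_apc.csv
  Published keyword-level total average peak volume (APC) values with 95%
  CI bounds for scientific/infodemic and fake-news-related search terms,
  transcribed printed columns (study window 2020-02-20..2020-05-06).

table1_annotations_synthetic.csv / table2_annotations_synthetic.csv
  SYNTHETIC reconstructions of the per-category I-scale point breakdowns.
  Only the published totals are known; these breakdowns were chosen to be
  consistent with the rubric's worked examples (e.g. "COVID" generic=1,
  "coronavirus China" discriminatory=1, "coronavirus bill gates"
  misinformative=1, "coronavirus uv" other=1) and to sum to each printed
  total. They are annotation data, not code, and not original study data.

table4_hashtags.csv
  Published hashtag post counts for seven virus-name hashtags with a
  scientific/infodemic group label.

table3_country_hashtags.csv
  Published per-country hashtag totals (raw counts; display convention is
  multiples of 100,000).

events.csv
  Event log of dated news events referenced in spike narratives.
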