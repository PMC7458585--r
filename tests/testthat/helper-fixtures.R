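# Shared fixture builders: everything is constructed in code; the bundled
# extdata tables are reached through infodemic_example().

fixture_path <- function(file) infodemic_example(file)

# A minimal valid annotation row with overridable category points.
make_annotation <- function(moniker = "test-moniker", generic = 0,
                            misinformative = 0, discriminatory = 0,
                            deviant = 0, other = 0) {
  data.frame(moniker = moniker, generic = generic,
             misinformative = misinformative,
             discriminatory = discriminatory, deviant = deviant,
             other = other, stringsAsFactors = FALSE)
}

# Daily RSV series from a bare value vector.
make_series <- function(values, keyword = "q", geo = "GLOBAL",
                        start = "2020-02-20", normalized = TRUE) {
  rsv_series(keyword, geo,
             seq(as.Date(start), by = "day", length.out = length(values)),
             values, normalized = normalized)
}

# The published keyword APC table and its synthetic annotation breakdown.
table1_estimates <- function() read_apc_table(fixture_path("table1_google_apc.csv"))
table1_scores <- function()
  iscale(read_annotations(fixture_path("table1_annotations_synthetic.csv")))
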