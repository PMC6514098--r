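# Regenerates the plain-text fixtures under inst/extdata from the in-code
# defaults.  Run from the package root with: Rscript data-raw/make_fixtures.R
devtools::load_all(".")

dir.create("inst/extdata", showWarnings = FALSE, recursive = TRUE)
write_probe_panel(azf_panel(), "inst/extdata/azf_panel.tsv")
write_cnv_catalogue(azf_catalogue(), "inst/extdata/azf_catalogue.json")
readr::write_tsv(azf_class_counts(), "inst/extdata/cohort_class_counts.tsv")
readr::write_tsv(azf_composite_counts(), "inst/extdata/cohort_composite_counts.tsv")
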