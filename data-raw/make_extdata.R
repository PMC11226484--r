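# Regenerates the packaged default knowledge base CSVs from paper_kb().
pkgload::load_all(".", quiet = TRUE)
kb_write(paper_kb(), "inst/extdata/kb")
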