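.datatable.aware <- TRUE

utils::globalVariables(c(
  "chrom", "chrom1", "chrom2", "start1", "end1", "start2", "end2", "name",
  "bin", "cluster", "sample", "peak", "overlap", "ann_start", "count",
  "resolution", "key"))
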