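# In-code fixtures: a tiny two-group, two-replicate record set over the
# variant peptides plus H4, and writers for file-based IO tests.

tiny_records <- function() {
  tibble::tibble(
    sample_group = rep(c("root", "shoot"), each = 6),
    replicate = rep(c(1L, 1L, 1L, 2L, 2L, 2L), 2),
    region_id = rep(c("H3.1K27-R40", "H3.3K27-R40", "H4G4-R17"), 4),
    modifications = rep(c("K27:me1", "K27:me1;K36:me2", "K5:ac;K8:ac"), 4),
    peak_area = c(10, 30, 5, 12, 28, 6, 30, 10, 8, 28, 12, 9)
  )
}

write_fixture_table <- function(records, path, delim = "\t") {
  df <- records
  names(df) <- c("sample_group", "replicate", "region_id", "modifications",
                 "peak_area")
  lines <- c(paste(names(df), collapse = delim),
             apply(df, 1L, function(r) paste(r, collapse = delim)))
  writeLines(lines, path)
  path
}
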