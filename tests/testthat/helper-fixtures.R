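# Small in-code fixtures shared across test files.

# Abundance matrix from a plain numeric matrix (rownames = accessions).
tiny_am <- function(m, kind = "intensity", scale = "linear") {
  df <- tibble::as_tibble(as.data.frame(m), rownames = "protein_id")
  abundance_matrix(df, value_kind = kind, scale = scale)
}

tiny_samples <- function(sample_ids, groups,
                         bait = NA_character_, control = FALSE) {
  tibble::tibble(sample_id = sample_ids, sample_group = groups,
                 bait_uniprot = bait, is_control = control,
                 acquisition_order = seq_along(sample_ids))
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# 4-sample, 2-group sample table file on disk.
write_sample_table_tmp <- function() {
  write_lines_tmp(c(
    "sample\tgroup\tbait_uniprot\tis_control",
    "S1\tA\t\tfalse", "S2\tA\t\tfalse",
    "S3\tB\tP11111\tfalse", "S4\tB\tP11111\tfalse"
  ))
}
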