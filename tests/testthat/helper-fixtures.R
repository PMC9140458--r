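# Build a catalog from in-code rows by round-tripping through the text
# reader, so synthetic fixtures exercise the same path as user files.
make_catalog <- function(...) {
  rows <- list(...)
  cols <- c("name", "abbreviation", "formula", "glycosidic_bond",
            "sugar_mod", "product_overrides", "printed_precursor",
            "printed_product", "alt_precursor", "alt_product",
            "family", "provenance")
  df <- do.call(rbind, lapply(rows, function(r) {
    full <- stats::setNames(as.list(rep("", length(cols))), cols)
    full[names(r)] <- r
    as.data.frame(full, stringsAsFactors = FALSE)
  }))
  if (!all(nzchar(df$sugar_mod))) df$sugar_mod[!nzchar(df$sugar_mod)] <- "none"
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  read_catalog(path)
}

builtin_subset <- function(abbrs) {
  cat <- builtin_catalog()
  cat[match(abbrs, cat$abbreviation), , drop = FALSE]
}
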