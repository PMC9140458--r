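# Nucleoside catalog: one row per species. Printed transition values from
# the literature are stored verbatim alongside the molecular formula and
# are never silently "corrected"; validate_against_printed() reconciles
# them against the computed transitions.

.catalog_cols <- c("name", "abbreviation", "formula", "glycosidic_bond",
                   "sugar_mod", "product_overrides", "printed_precursor",
                   "printed_product", "alt_precursor", "alt_product",
                   "family", "provenance")

.cat_env <- new.env(parent = emptyenv())

#' Read a nucleoside catalog from delimited text
#'
#' Accepts comma- or tab-delimited UTF-8 text with a header. Required
#' columns: `name`, `abbreviation`, `formula`, `glycosidic_bond` (`N` or
#' `C`); optional: `sugar_mod` (`none` or `2'-O-methyl`),
#' `product_overrides` (semicolon-separated m/z values for species whose
#' product ions are data rather than a neutral-loss rule, e.g. the
#' pseudouridine family), `printed_precursor`, `printed_product`,
#' `alt_precursor`, `alt_product` (alternate printed values where sources
#' disagree), `family`, `provenance`.
#'
#' Rows duplicated by abbreviation are merged when their formulas agree
#' (provenances concatenated); conflicting formulas are an error.
#' C-glycosides without product overrides are retained but flagged
#' un-monitorable (`monitorable = FALSE`): the protonated nucleobase is
#' not observed for such species.
#'
#' @param path File path.
#' @return A `nucleoside_catalog` data frame.
#' @export
read_catalog <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", fill = TRUE,
                          encoding = "UTF-8")
  need <- c("name", "abbreviation", "formula", "glycosidic_bond")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("catalog missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in setdiff(.catalog_cols, names(df)))
    df[[col]] <- character(nrow(df))
  df <- df[, .catalog_cols]
  for (col in .catalog_cols) {
    v <- as.character(df[[col]])
    v[is.na(v)] <- ""
    df[[col]] <- trimws(v)
  }
  df$sugar_mod[df$sugar_mod == ""] <- "none"
  as_catalog(df)
}

# Validate and classify a raw catalog data frame.
as_catalog <- function(df, source = "user") {
  bad_bond <- !df$glycosidic_bond %in% c("N", "C")
  if (any(bad_bond))
    stop(sprintf("unknown glycosidic_bond value '%s' for %s",
                 df$glycosidic_bond[bad_bond][1],
                 df$abbreviation[bad_bond][1]), call. = FALSE)
  if (!all(df$sugar_mod %in% c("none", "2'-O-methyl")))
    stop("sugar_mod must be 'none' or \"2'-O-methyl\"", call. = FALSE)
  for (i in seq_len(nrow(df))) {
    f <- tryCatch(parse_formula(df$formula[i]), error = function(e)
      stop(sprintf("row %d (%s): %s", i, df$abbreviation[i],
                   conditionMessage(e)), call. = FALSE))
    if (df$sugar_mod[i] == "2'-O-methyl") {
      ok <- tryCatch({subtract_loss(f, "C6H10O4"); TRUE},
                     error = function(e) FALSE)
      if (!ok)
        stop(sprintf("row %d (%s): 2'-O-methyl species must contain C6H10O4",
                     i, df$abbreviation[i]), call. = FALSE)
    }
  }
  # merge duplicates by abbreviation
  if (anyDuplicated(df$abbreviation)) {
    keep <- !duplicated(df$abbreviation)
    for (ab in unique(df$abbreviation[duplicated(df$abbreviation)])) {
      rows <- which(df$abbreviation == ab)
      if (length(unique(df$formula[rows])) > 1L)
        stop(sprintf("duplicate abbreviation '%s' with conflicting formulas: %s",
                     ab, paste(unique(df$formula[rows]), collapse = " vs ")),
             call. = FALSE)
      first <- rows[1]
      prov <- unique(unlist(strsplit(df$provenance[rows], ";")))
      df$provenance[first] <- paste(prov[nzchar(prov)], collapse = ";")
    }
    df <- df[keep, , drop = FALSE]
  }
  df$monitorable <- !(df$glycosidic_bond == "C" & df$product_overrides == "")
  rownames(df) <- NULL
  structure(df, class = c("nucleoside_catalog", "data.frame"),
            source = source)
}

#' @export
print.nucleoside_catalog <- function(x, ...) {
  cat(sprintf("<nucleoside catalog: %d species (%d monitorable)>\n",
              nrow(x), sum(x$monitorable)))
  print.data.frame(utils::head(as.data.frame(
    x[, c("abbreviation", "formula", "glycosidic_bond", "sugar_mod",
          "printed_precursor", "printed_product")]), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Write a catalog to tab-delimited text
#'
#' Canonical writer; `read_catalog(write_catalog(c, path))` round-trips.
#'
#' @param catalog A `nucleoside_catalog`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  df <- as.data.frame(catalog)[, .catalog_cols]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' The bundled nucleoside catalog
#'
#' The packaged catalog of commonly monitored modified ribonucleosides:
#' structural-isomer groups, mass-analog groups and isotopic-crosstalk
#' groups, together with the canonical nucleosides (A, C, G, U), inosine
#' and pseudouridine. Printed precursor/product values from the source
#' tables are carried verbatim, including a small number of
#' internally inconsistent entries (see [known_discrepancies()]);
#' alternate printed values appear in `alt_precursor` / `alt_product`.
#' Pseudouridine-family product ions are data overrides: pseudouridine
#' itself is monitored at 209/179/155, its methyl derivatives at 179, and
#' the aminocarboxypropyl derivatives at 214/228.
#'
#' @return A `nucleoside_catalog`.
#' @examples
#' cat <- builtin_catalog()
#' catalog_lookup(cat, "m6,6A")$formula
#' @export
builtin_catalog <- function() {
  if (!is.null(.cat_env$builtin)) return(.cat_env$builtin)
  path <- system.file("extdata", "nucleosides.tsv", package = "mrmscreen",
                      mustWork = TRUE)
  cat <- read_catalog(path)
  attr(cat, "source") <- "builtin"
  .cat_env$builtin <- cat
  cat
}

#' Look up a species by abbreviation
#'
#' @param catalog A `nucleoside_catalog`.
#' @param abbreviation Short code, e.g. `"m1A"`.
#' @return The matching one-row data frame, or `NULL` if absent.
#' @export
catalog_lookup <- function(catalog, abbreviation) {
  i <- match(abbreviation, catalog$abbreviation)
  if (is.na(i)) return(NULL)
  catalog[i, , drop = FALSE]
}

.parse_overrides <- function(s) {
  if (is.na(s) || !nzchar(s)) return(numeric(0))
  as.numeric(strsplit(s, ";")[[1]])
}

#' Enumerated printed-value discrepancies in the bundled catalog
#'
#' The bundled catalog carries printed transition values verbatim, and a
#' handful are internally inconsistent with the printed molecular
#' formulas (or between source tables). This fixture enumerates them; it
#' is exactly the output of [validate_against_printed()] on the builtin
#' catalog and is stable across releases.
#'
#' @return Data frame with columns `abbreviation`, `field`, `printed`,
#'   `computed`.
#' @export
known_discrepancies <- function() {
  data.frame(
    abbreviation = c("m2,8A", "m6,6A", "f6A", "m6t6A", "m6t6A",
                     "mchm5U", "mcmo5U"),
    field = c("precursor", "precursor", "precursor", "precursor",
              "product", "product", "product"),
    printed = c(269.1, 269.1, 269.1, 427.2, 295, 297, 297),
    computed = c(296.1, 296.1, 296.1, 413.1, 281, 201, 201),
    stringsAsFactors = FALSE
  )
}

#' Reconcile computed transitions against printed values
#'
#' For every species with printed precursor/product values (including
#' alternates), compares the computed nominal transition (precursor to 1
#' decimal, product to integer) against the printed one. Discrepancies are
#' data, not failures: the bundled catalog is expected to yield exactly
#' the [known_discrepancies()] list.
#'
#' @param catalog A `nucleoside_catalog`.
#' @param conv A [mass_convention()].
#' @return Data frame with columns `abbreviation`, `field`, `printed`,
#'   `computed`; zero rows when everything matches.
#' @export
validate_against_printed <- function(catalog, conv = mass_convention()) {
  out <- list()
  for (i in seq_len(nrow(catalog))) {
    sp <- catalog[i, , drop = FALSE]
    prec <- precursor_ion(sp, conv)
    prods <- tryCatch(product_ions(sp, conv), error = function(e) NULL)
    prod_nominal <- if (is.null(prods)) numeric(0) else prods$nominal
    check <- function(printed_str, field) {
      if (!nzchar(printed_str)) return(NULL)
      printed <- as.numeric(printed_str)
      if (field == "precursor") {
        if (abs(printed - prec$nominal) > 1e-9)
          return(data.frame(abbreviation = sp$abbreviation, field = field,
                            printed = printed, computed = prec$nominal,
                            stringsAsFactors = FALSE))
      } else {
        if (!length(prod_nominal)) return(NULL)
        if (!any(abs(printed - prod_nominal) < 1e-9))
          return(data.frame(abbreviation = sp$abbreviation, field = field,
                            printed = printed, computed = prod_nominal[1],
                            stringsAsFactors = FALSE))
      }
      NULL
    }
    out <- c(out,
             list(check(sp$printed_precursor, "precursor"),
                  check(sp$printed_product, "product"),
                  check(sp$alt_precursor, "precursor"),
                  check(sp$alt_product, "product")))
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(abbreviation = character(0), field = character(0),
                      printed = numeric(0), computed = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
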