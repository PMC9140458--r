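# Pairwise misidentification screening.
#
# Three finding classes, after the standard typology for unit-resolution
# MRM assays of nucleosides:
#   Type I   - structural isomers (identical formula) sharing a channel;
#   Type II  - mass-analogs: different formulas whose precursor and
#              product masses each differ by less than the resolution;
#   Type III - isotopic crosstalk: a heavy isotopologue (+k Da, k = 1, 2,
#              mainly 13C and 34S) of one species landing in another
#              species' channel, with the heavy atoms retained in the
#              product fragment on both quadrupoles.
#
# Channel comparison uses exact masses against the resolution window, not
# equality of rounded values, so rounding-boundary pairs are not missed.
# The per-unit isotopologue shift is taken as the 13C-12C mass difference
# (1.003355 Da), the dominant contributor; at a 0.5 Da window the
# difference from other heavy isotopes' shifts is immaterial.

.SHIFT_UNIT <- 1.003355

#' Screening parameters
#'
#' @param resolution Full mass tolerance per quadrupole in Da
#'   (default 0.5, the unit resolution of a triple quadrupole).
#' @param max_shift Largest isotopologue shift considered (default 2;
#'   one- and two-Da shifts cover 13C and 34S crosstalk).
#' @param min_crosstalk_abundance Relative-abundance floor for reporting
#'   Type III findings (default 0.001: keeps 13C +1 and 34S +2 crosstalk,
#'   suppresses 2H/17O noise).
#' @param rt_window Optional co-elution window in minutes; used only when
#'   a retention table is supplied to [screen_catalog()].
#' @param include_partial Also report "partial" crosstalk (precursor
#'   shifted, product not: heavy atoms in the neutral loss). Off by
#'   default; no published assay monitors such channels.
#' @return A `screening_params` object.
#' @export
screening_params <- function(resolution = 0.5, max_shift = 2L,
                             min_crosstalk_abundance = 0.001,
                             rt_window = NULL, include_partial = FALSE) {
  stopifnot(resolution > 0, max_shift >= 1,
            min_crosstalk_abundance >= 0, min_crosstalk_abundance <= 1)
  structure(list(resolution = resolution, max_shift = as.integer(max_shift),
                 min_crosstalk_abundance = min_crosstalk_abundance,
                 rt_window = rt_window,
                 include_partial = isTRUE(include_partial)),
            class = "screening_params")
}

# Product-mass delta between two channels: exact when both sides have an
# exact product mass, nominal when either side is a printed override.
.product_delta <- function(a, b) {
  if (is.na(a$product_exact) || is.na(b$product_exact))
    abs(a$product_nominal - b$product_nominal)
  else abs(a$product_exact - b$product_exact)
}

#' Do two transitions share a channel at the given resolution?
#'
#' @param a,b Single transitions: lists or one-row data frames with
#'   `precursor_exact`, `product_exact`, `product_nominal`.
#' @param params A [screening_params()].
#' @return Logical.
#' @export
same_channel <- function(a, b, params = screening_params()) {
  abs(a$precursor_exact - b$precursor_exact) < params$resolution &&
    .product_delta(a, b) < params$resolution
}

# Per-species screening info: channels plus fragment-conditional
# crosstalk factors for k = 1..max_shift.
.species_info <- function(catalog, params, conv, table) {
  trans <- transitions_for_catalog(catalog, conv, table)
  info <- list()
  for (i in seq_len(nrow(catalog))) {
    sp <- catalog[i, , drop = FALSE]
    ch <- trans[trans$abbreviation == sp$abbreviation, , drop = FALSE]
    ct <- rep(NA_real_, params$max_shift)
    pt <- rep(NA_real_, params$max_shift)
    if (nrow(ch) && ch$rule[1] != "override") {
      loss <- if (ch$rule[1] == "methylribose-loss") METHYLRIBOSE_LOSS
              else RIBOSE_LOSS
      base <- subtract_loss(sp$formula, loss)
      for (k in seq_len(params$max_shift)) {
        ct[k] <- fragment_crosstalk_factor(base, loss, k, table)
        pt[k] <- partial_crosstalk_factor(base, loss, k, table)
      }
    }
    info[[sp$abbreviation]] <- list(
      abbreviation = sp$abbreviation,
      formula = write_formula(parse_formula(sp$formula)),
      channels = ch, crosstalk = ct, partial = pt)
  }
  list(info = info, skipped = attr(trans, "skipped"), transitions = trans)
}

.finding_row <- function(type, target, interferer, tgt_ch, k = NA_integer_,
                         abundance = NA_real_, dprec, dprod) {
  data.frame(type = type, target = target, interferer = interferer,
             shared_precursor = tgt_ch$precursor_nominal,
             shared_product = tgt_ch$product_nominal,
             delta_precursor = dprec, delta_product = dprod,
             k = k, crosstalk_abundance = abundance,
             stringsAsFactors = FALSE)
}

# Core pairwise classifier over precomputed species info.
.classify_infos <- function(ia, ib, params) {
  findings <- list(); resolvable <- list()
  cha <- ia$channels; chb <- ib$channels
  if (!nrow(cha) || !nrow(chb))
    return(list(findings = NULL, resolvable = NULL))
  same_formula <- identical(ia$formula, ib$formula)
  shared_any <- FALSE
  for (i in seq_len(nrow(cha))) for (j in seq_len(nrow(chb))) {
    ta <- cha[i, , drop = FALSE]; tb <- chb[j, , drop = FALSE]
    dprec <- abs(ta$precursor_exact - tb$precursor_exact)
    dprod <- .product_delta(ta, tb)
    if (dprec < params$resolution && dprod < params$resolution) {
      shared_any <- TRUE
      if (same_formula) {
        findings[[length(findings) + 1L]] <- .finding_row(
          "I", ia$abbreviation, ib$abbreviation, ta,
          dprec = dprec, dprod = dprod)
      } else {
        findings[[length(findings) + 1L]] <- .finding_row(
          "II", ia$abbreviation, ib$abbreviation, ta,
          dprec = dprec, dprod = dprod)
      }
    }
  }
  if (same_formula && !shared_any) {
    resolvable[[1L]] <- data.frame(
      species_a = ia$abbreviation, species_b = ib$abbreviation,
      formula = ia$formula, stringsAsFactors = FALSE)
  }
  # Type III, both directions (interferer -> target)
  for (dir in list(c(1, 2), c(2, 1))) {
    ii <- list(ia, ib)[[dir[1]]]; it <- list(ia, ib)[[dir[2]]]
    chi <- ii$channels; cht <- it$channels
    for (i in seq_len(nrow(chi))) {
      ti <- chi[i, , drop = FALSE]
      if (is.na(ti$product_exact)) next  # override: no fragment formula
      for (j in seq_len(nrow(cht))) {
        tt <- cht[j, , drop = FALSE]
        for (k in seq_len(params$max_shift)) {
          dprec <- abs(ti$precursor_exact + k * .SHIFT_UNIT -
                         tt$precursor_exact)
          tprod <- if (is.na(tt$product_exact)) tt$product_nominal
                   else tt$product_exact
          dprod <- abs(ti$product_exact + k * .SHIFT_UNIT - tprod)
          if (dprec < params$resolution && dprod < params$resolution) {
            ab <- ii$crosstalk[k]
            if (!is.na(ab) && ab >= params$min_crosstalk_abundance) {
              findings[[length(findings) + 1L]] <- .finding_row(
                "III", it$abbreviation, ii$abbreviation, tt, k = k,
                abundance = ab, dprec = dprec, dprod = dprod)
            }
          }
          if (params$include_partial) {
            dprec_p <- abs(ti$precursor_exact + k * .SHIFT_UNIT -
                             tt$precursor_exact)
            dprod_p <- .product_delta(ti, tt)
            ab_p <- ii$partial[k]
            if (dprec_p < params$resolution &&
                dprod_p < params$resolution &&
                !is.na(ab_p) && ab_p >= params$min_crosstalk_abundance) {
              findings[[length(findings) + 1L]] <- .finding_row(
                "III-partial", it$abbreviation, ii$abbreviation, tt, k = k,
                abundance = ab_p, dprec = dprec_p, dprod = dprod_p)
            }
          }
        }
      }
    }
  }
  list(findings = if (length(findings)) do.call(rbind, findings) else NULL,
       resolvable = if (length(resolvable)) resolvable[[1]] else NULL)
}

#' Classify one pair of species
#'
#' Emits zero or more interference findings for an unordered pair:
#' Type I and II once per shared channel, Type III directionally with
#' both directions evaluated. Structural isomers whose product ions
#' differ (e.g. a 2'-O-methyl species against a base-methylated isomer,
#' or pseudouridine against uridine) are not findings; they are returned
#' separately as resolvable isomers.
#'
#' @param a,b One-row `nucleoside_catalog` subsets.
#' @param params A [screening_params()].
#' @param conv A [mass_convention()].
#' @param table An [isotope_table()].
#' @return List with `findings` (data frame, possibly empty) and
#'   `resolvable` (data frame or NULL).
#' @export
classify_pair <- function(a, b, params = screening_params(),
                          conv = mass_convention(),
                          table = isotope_table()) {
  if (identical(a$abbreviation, b$abbreviation))
    return(list(findings = .empty_findings(), resolvable = NULL))
  pair_cat <- as_catalog(rbind(as.data.frame(a)[, .catalog_cols],
                               as.data.frame(b)[, .catalog_cols]))
  si <- .species_info(pair_cat, params, conv, table)
  res <- .classify_infos(si$info[[a$abbreviation]],
                         si$info[[b$abbreviation]], params)
  if (is.null(res$findings))
    res$findings <- .empty_findings()
  res
}

.empty_findings <- function() {
  data.frame(type = character(0), target = character(0),
             interferer = character(0), shared_precursor = numeric(0),
             shared_product = numeric(0), delta_precursor = numeric(0),
             delta_product = numeric(0), k = integer(0),
             crosstalk_abundance = numeric(0), stringsAsFactors = FALSE)
}

#' Screen a catalog (or panel) for misidentification risks
#'
#' Classifies every unordered pair of species, groups findings by shared
#' nominal channel, and reports species that could not be assigned
#' transitions. With a retention table, findings between species whose
#' retention times differ by less than `rt_window` are flagged
#' co-eluting.
#'
#' @param catalog A `nucleoside_catalog` (the panel to screen).
#' @param params A [screening_params()].
#' @param rt Optional retention table: data frame with columns
#'   `abbreviation` and `rt` (minutes, or ordinal ranks).
#' @param conv A [mass_convention()].
#' @param table An [isotope_table()].
#' @return A `screening_report`: list with `findings`, `resolvable`,
#'   `channel_groups`, `skipped`, `params`, `n_species`.
#' @examples
#' panel <- builtin_catalog()
#' rep5 <- screen_catalog(panel[panel$abbreviation %in%
#'   c("s2U", "s4U", "ho5U", "m5D", "s2C"), ])
#' rep5$channel_groups
#' @export
screen_catalog <- function(catalog, params = screening_params(), rt = NULL,
                           conv = mass_convention(),
                           table = isotope_table()) {
  if (!nrow(catalog)) stop("catalog is empty", call. = FALSE)
  si <- .species_info(catalog, params, conv, table)
  abbrs <- catalog$abbreviation
  findings <- list(); resolvable <- list()
  if (length(abbrs) > 1L) {
    for (i in 1:(length(abbrs) - 1L)) for (j in (i + 1L):length(abbrs)) {
      res <- .classify_infos(si$info[[abbrs[i]]], si$info[[abbrs[j]]],
                             params)
      if (!is.null(res$findings))
        findings[[length(findings) + 1L]] <- res$findings
      if (!is.null(res$resolvable))
        resolvable[[length(resolvable) + 1L]] <- res$resolvable
    }
  }
  findings <- if (length(findings)) do.call(rbind, findings) else
    .empty_findings()
  resolvable <- if (length(resolvable)) do.call(rbind, resolvable) else
    data.frame(species_a = character(0), species_b = character(0),
               formula = character(0), stringsAsFactors = FALSE)
  if (!is.null(rt) && !is.null(params$rt_window) && nrow(findings)) {
    rt_of <- stats::setNames(rt$rt, rt$abbreviation)
    findings$co_elution <- abs(rt_of[findings$target] -
                                 rt_of[findings$interferer]) <
      params$rt_window
  } else if (nrow(findings)) {
    findings$co_elution <- NA
  } else {
    findings$co_elution <- logical(0)
  }
  ord <- order(findings$shared_precursor, findings$shared_product,
               findings$type, findings$target, findings$interferer,
               findings$k)
  findings <- findings[ord, , drop = FALSE]
  rownames(findings) <- NULL
  structure(list(findings = findings, resolvable = resolvable,
                 channel_groups = .channel_groups(findings),
                 skipped = si$skipped, params = params,
                 n_species = nrow(catalog)),
            class = "screening_report")
}

# Group findings by shared nominal channel.
.channel_groups <- function(findings) {
  if (!nrow(findings))
    return(data.frame(precursor = numeric(0), product = numeric(0),
                      n_members = integer(0), members = character(0),
                      types = character(0), stringsAsFactors = FALSE))
  key <- paste(findings$shared_precursor, findings$shared_product)
  rows <- lapply(unique(key), function(kk) {
    sub <- findings[key == kk, , drop = FALSE]
    members <- sort(unique(c(sub$target, sub$interferer)))
    data.frame(precursor = sub$shared_precursor[1],
               product = sub$shared_product[1],
               n_members = length(members),
               members = paste(members, collapse = ";"),
               types = paste(sort(unique(sub$type)), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$precursor, out$product), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("<screening report: %d species, %d findings, %d channel groups>\n",
              x$n_species, nrow(x$findings), nrow(x$channel_groups)))
  if (nrow(x$channel_groups)) print.data.frame(x$channel_groups)
  if (nrow(x$resolvable))
    cat(sprintf("resolvable isomer pairs: %d\n", nrow(x$resolvable)))
  if (nrow(x$skipped))
    cat(sprintf("skipped species: %s\n",
                paste(x$skipped$abbreviation, collapse = ", ")))
  invisible(x)
}

#' Serialize a screening report
#'
#' `"tsv"` writes the findings table with channel groups and skipped
#' species as commented header sections; `"json"` writes a versioned
#' document that [read_report()] restores.
#'
#' @param report A `screening_report`.
#' @param format `"tsv"` or `"json"`.
#' @param path Output file; `""` returns/prints to stdout.
#' @return `path` invisibly (or the serialized text when `path = ""`).
#' @export
write_report <- function(report, format = c("tsv", "json"), path = "") {
  format <- match.arg(format)
  if (format == "json") {
    doc <- list(schema_version = "1.0",
                n_species = report$n_species,
                params = unclass(report$params),
                findings = report$findings,
                resolvable = report$resolvable,
                channel_groups = report$channel_groups,
                skipped = report$skipped)
    txt <- jsonlite::toJSON(doc, dataframe = "rows", auto_unbox = TRUE,
                            digits = NA, null = "null", pretty = TRUE)
    if (path == "") return(invisible(as.character(txt)))
    writeLines(txt, path)
    return(invisible(path))
  }
  con <- if (path == "") stdout() else file(path, open = "wt")
  if (path != "") on.exit(close(con))
  writeLines(sprintf("# screening report: %d species, %d findings",
                     report$n_species, nrow(report$findings)), con)
  if (nrow(report$channel_groups)) {
    writeLines("# channel groups (precursor product n_members members types):",
               con)
    writeLines(sprintf("#   %s %s %d %s %s",
                       format(report$channel_groups$precursor, nsmall = 1),
                       report$channel_groups$product,
                       report$channel_groups$n_members,
                       report$channel_groups$members,
                       report$channel_groups$types), con)
  }
  if (nrow(report$skipped))
    writeLines(sprintf("# skipped: %s", paste(report$skipped$abbreviation,
                                              collapse = ", ")), con)
  utils::write.table(report$findings, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(doc$schema_version))
    stop("not a screening report JSON document", call. = FALSE)
  fnd <- if (length(doc$findings)) as.data.frame(doc$findings) else
    .empty_findings()
  structure(list(findings = fnd,
                 resolvable = as.data.frame(doc$resolvable),
                 channel_groups = as.data.frame(doc$channel_groups),
                 skipped = as.data.frame(doc$skipped),
                 params = do.call(screening_params,
                                  doc$params[!vapply(doc$params, is.null,
                                                     logical(1))]),
                 n_species = doc$n_species),
            class = "screening_report")
}
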