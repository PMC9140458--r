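# Independent oracles used to cross-check the package implementation.
# They deliberately avoid the package's code paths: formula parsing is a
# bare regex, masses come from locally declared constants, isotopologue
# distributions are computed by explicit multinomial enumeration over
# isotope assignments (not polynomial convolution), and the brute-force
# screen is a direct double loop.

oracle_monoisotopic <- local({
  masses <- c(H = 1.0078250319, C = 12, N = 14.0030740052,
              O = 15.9949146221, S = 31.97207069, P = 30.97376151)
  function(formula) {
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
    toks <- regmatches(formula, list(m))[[1]]
    syms <- sub("[0-9]*$", "", toks)
    n <- as.integer(ifelse(grepl("[0-9]", toks), sub("^[A-Za-z]+", "", toks), 1))
    sum(masses[syms] * n)
  }
})

oracle_counts <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  syms <- sub("[0-9]*$", "", toks)
  n <- as.integer(ifelse(grepl("[0-9]", toks), sub("^[A-Za-z]+", "", toks), 1))
  tapply(n, factor(syms, levels = unique(syms)), sum)
}

# Enumerate isotope compositions of n atoms of one element; returns the
# aggregated shift distribution (vector indexed 0..max_k).
oracle_element_dist <- function(symbol, n, max_k, table) {
  sub <- table[table$symbol == symbol, , drop = FALSE]
  probs <- sub$abundance; offs <- sub$offset
  out <- numeric(max_k + 1L)
  if (n == 0) { out[1] <- 1; return(out) }
  compositions <- function(n, m) {
    if (m == 1) return(matrix(n, 1, 1))
    do.call(rbind, lapply(0:n, function(i)
      cbind(i, compositions(n - i, m - 1))))
  }
  comps <- compositions(n, length(probs))
  for (r in seq_len(nrow(comps))) {
    k <- sum(comps[r, ] * offs)
    if (k <= max_k)
      out[k + 1L] <- out[k + 1L] + stats::dmultinom(comps[r, ], prob = probs)
  }
  out
}

# Combine per-element enumerated distributions over an explicit grid of
# per-element shifts (no convolution code shared with the package).
oracle_formula_dist <- function(formula, max_k, table = isotope_table()) {
  cnt <- oracle_counts(formula)
  dists <- lapply(names(cnt), function(s)
    oracle_element_dist(s, cnt[[s]], max_k, table))
  grid <- do.call(expand.grid, rep(list(0:max_k), length(dists)))
  out <- numeric(max_k + 1L)
  for (r in seq_len(nrow(grid))) {
    ks <- as.integer(grid[r, ])
    tot <- sum(ks)
    if (tot > max_k) next
    p <- prod(vapply(seq_along(dists), function(i) dists[[i]][ks[i] + 1L],
                     numeric(1)))
    out[tot + 1L] <- out[tot + 1L] + p
  }
  out
}

# Heavy-atom placements restricted to the retained base fragment: the
# base carries all k heavies, every atom of the loss is light.
oracle_crosstalk <- function(base, loss, k, table = isotope_table()) {
  pb <- oracle_formula_dist(base, k, table)
  light_loss <- 1
  cnt <- oracle_counts(loss)
  for (s in names(cnt)) {
    sub <- table[table$symbol == s & table$offset == 0L, ]
    light_loss <- light_loss * sub$abundance^cnt[[s]]
  }
  pb[k + 1L] * light_loss
}

round_up_half <- function(x, d = 0) floor(x * 10^d + 0.5) / 10^d

# Channels computed directly from catalog fields with local constants.
oracle_channels <- function(sp) {
  prec <- oracle_monoisotopic(sp$formula) + 1.00783
  ov <- if (nzchar(sp$product_overrides))
    as.numeric(strsplit(sp$product_overrides, ";")[[1]]) else numeric(0)
  if (length(ov)) {
    return(data.frame(prec = prec, prod_exact = NA_real_, prod_nom = ov,
                      loss = NA_character_, stringsAsFactors = FALSE))
  }
  if (sp$glycosidic_bond == "C") return(NULL)
  loss <- if (sp$sugar_mod == "2'-O-methyl") "C6H10O4" else "C5H8O4"
  pe <- prec - oracle_monoisotopic(loss)
  data.frame(prec = prec, prod_exact = pe, prod_nom = round_up_half(pe),
             loss = loss, stringsAsFactors = FALSE)
}

# Direct double-loop classifier over all channel pairs and shifts.
# Returns a character vector of canonical finding keys plus a named
# abundance vector for Type III.
oracle_screen <- function(panel_cat, params, table = isotope_table()) {
  n <- nrow(panel_cat)
  chans <- lapply(seq_len(n), function(i)
    oracle_channels(panel_cat[i, , drop = FALSE]))
  forms <- vapply(seq_len(n), function(i)
    paste(sort(sprintf("%s%d", names(oracle_counts(panel_cat$formula[i])),
                       oracle_counts(panel_cat$formula[i]))), collapse = ""),
    character(1))
  keys <- character(0); abunds <- numeric(0)
  prod_delta <- function(a, b) {
    if (is.na(a$prod_exact) || is.na(b$prod_exact))
      abs(a$prod_nom - b$prod_nom) else abs(a$prod_exact - b$prod_exact)
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ci <- chans[[i]]; cj <- chans[[j]]
    if (is.null(ci) || is.null(cj)) next
    if (i < j) {  # symmetric types once per unordered pair
      for (a in seq_len(nrow(ci))) for (b in seq_len(nrow(cj))) {
        ta <- ci[a, ]; tb <- cj[b, ]
        if (abs(ta$prec - tb$prec) < params$resolution &&
            prod_delta(ta, tb) < params$resolution) {
          type <- if (forms[i] == forms[j]) "I" else "II"
          keys <- c(keys, paste("sym", type,
                                panel_cat$abbreviation[i],
                                panel_cat$abbreviation[j],
                                round_up_half(ta$prec, 1), ta$prod_nom))
        }
      }
    }
    # directional crosstalk: i interferer, j target
    for (a in seq_len(nrow(ci))) {
      ta <- ci[a, ]
      if (is.na(ta$prod_exact)) next
      for (b in seq_len(nrow(cj))) {
        tb <- cj[b, ]
        tprod <- if (is.na(tb$prod_exact)) tb$prod_nom else tb$prod_exact
        for (k in seq_len(params$max_shift)) {
          if (abs(ta$prec + k * 1.003355 - tb$prec) < params$resolution &&
              abs(ta$prod_exact + k * 1.003355 - tprod) <
                params$resolution) {
            base <- write_formula(subtract_loss(panel_cat$formula[i],
                                                ta$loss))
            ab <- oracle_crosstalk(base, ta$loss, k, table)
            if (ab >= params$min_crosstalk_abundance) {
              key <- paste("III", panel_cat$abbreviation[j],
                           panel_cat$abbreviation[i], k,
                           round_up_half(tb$prec, 1), tb$prod_nom)
              keys <- c(keys, key)
              abunds[key] <- ab
            }
          }
        }
      }
    }
  }
  list(keys = sort(keys), abundances = abunds)
}

# Canonical keys for an implementation findings data frame.
finding_keys <- function(findings) {
  if (!nrow(findings)) return(character(0))
  keys <- character(nrow(findings))
  for (r in seq_len(nrow(findings))) {
    f <- findings[r, ]
    keys[r] <- if (f$type %in% c("I", "II")) {
      pair <- c(f$target, f$interferer)  # emitted in catalog order
      paste("sym", f$type, pair[1], pair[2], f$shared_precursor,
            f$shared_product)
    } else {
      paste(f$type, f$target, f$interferer, f$k, f$shared_precursor,
            f$shared_product)
    }
  }
  sort(keys)
}
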