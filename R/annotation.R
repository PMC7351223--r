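# Exact monoisotopic constants (Da)
MASS_PROTON <- 1.0072765
MASS_CL <- 34.9688527
MASS_H2O <- 18.0105646
MASS_NA <- 22.9897693
MASS_K <- 38.9637065
MASS_C13_SHIFT <- 1.0033548

#' Negative-mode adduct and isotopologue rules
#'
#' Each rule maps a neutral monoisotopic mass M to an observed m/z via
#' `mz = M * multiplicity + mass_delta` (single negative charge), and
#' inversely `M = (mz - mass_delta) / multiplicity`. The `rank` column is the
#' heuristic likelihood-of-observation priority used for annotation ranking:
#' deprotonation first, then water loss, chloride, the 2M dimer, sodium and
#' potassium exchange, the 13C isotopologues, and the bare radical anion
#' last.
#'
#' @return data.frame (name, multiplicity, mass_delta, rank).
#' @export
adduct_rules <- function() {
  data.frame(
    name = c("[M-H]-", "[M-H-H2O]-", "[M+Cl]-", "[2M-H]-",
             "[M-2H+Na]-", "[M-2H+K]-",
             "[M+C13-H]-", "[M+2C13-H]-", "[M+3C13-H]-", "[M]-"),
    multiplicity = c(1, 1, 1, 2, 1, 1, 1, 1, 1, 1),
    mass_delta = c(-MASS_PROTON,
                   -MASS_PROTON - MASS_H2O,
                   MASS_CL,
                   -MASS_PROTON,
                   MASS_NA - 2 * MASS_PROTON,
                   MASS_K - 2 * MASS_PROTON,
                   MASS_C13_SHIFT - MASS_PROTON,
                   2 * MASS_C13_SHIFT - MASS_PROTON,
                   3 * MASS_C13_SHIFT - MASS_PROTON,
                   0),
    rank = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  )
}

#' Candidate neutral masses for an observed m/z
#'
#' Applies the inverse adduct algebra `M = (mz - mass_delta) / multiplicity`
#' for every rule; rules implying a non-positive neutral mass are skipped.
#'
#' @param mz observed m/z (Da, negative mode, single charge).
#' @param rules an [adduct_rules()] table (or subset).
#' @return data.frame (adduct, multiplicity, mass_delta, rank,
#'   neutral_mass).
#' @export
neutral_mass_candidates <- function(mz, rules = adduct_rules()) {
  stopifnot(mz > 0)
  M <- (mz - rules$mass_delta) / rules$multiplicity
  keep <- M > 0
  data.frame(adduct = rules$name[keep],
             multiplicity = rules$multiplicity[keep],
             mass_delta = rules$mass_delta[keep],
             rank = rules$rank[keep],
             neutral_mass = M[keep])
}

#' Load the packaged compound table
#'
#' A curated table of compounds (name, formula, monoisotopic neutral mass,
#' source tag, class) standing in for full public-database parsing; sorted by
#' mass for binary-search lookup.
#'
#' @param path optional path to a CSV with the same columns.
#' @return data.frame sorted by `monoisotopic_mass`.
#' @export
load_compound_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "compounds.csv", package = "ftdkit")
  }
  comp <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "formula", "monoisotopic_mass") %in% names(comp)),
            all(comp$monoisotopic_mass > 0))
  comp[order(comp$monoisotopic_mass), , drop = FALSE]
}

#' Load the packaged annotation-name blocklist
#'
#' One token per line; records whose name or formula contains a token are
#' discarded as implausible putative labels (R-groups, polymers, exotic
#' elements).
#'
#' @param path optional path to a plain-text token file.
#' @return Character vector of tokens.
#' @export
load_name_blocklist <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "name_blocklist.txt", package = "ftdkit")
  }
  tok <- readLines(path)
  tok[nzchar(trimws(tok))]
}

#' Match candidate neutral masses against a compound table
#'
#' Returns every (adduct rule, compound) pair whose implied neutral mass is
#' within `ppm_max` parts per million of the compound's monoisotopic mass
#' (|implied - compound| / compound * 1e6 <= ppm_max); a mass-only match is
#' identification level 3. Lookup is by binary search on the mass-sorted
#' table.
#'
#' @param candidates a [neutral_mass_candidates()] data.frame.
#' @param compounds a [load_compound_table()] data.frame (mass-sorted).
#' @param ppm_max ppm tolerance (default 5).
#' @return data.frame (adduct, rank, neutral_mass, name, formula,
#'   compound_mass, source, ppm_error).
#' @export
match_database <- function(candidates, compounds, ppm_max = 5) {
  if (!nrow(compounds)) stop("empty compound table")
  masses <- compounds$monoisotopic_mass
  if (is.unsorted(masses)) {
    compounds <- compounds[order(masses), , drop = FALSE]
    masses <- compounds$monoisotopic_mass
  }
  out <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    M <- candidates$neutral_mass[i]
    # |M - c| <= c * ppm_max*1e-6  <=>  c in [M/(1+tol), M/(1-tol)];
    # search a slightly widened window, then filter on the exact ppm value
    tol <- ppm_max * 1e-6
    lo <- findInterval(M / (1 + 2 * tol), masses, left.open = TRUE) + 1L
    hi <- findInterval(M / (1 - 2 * tol), masses)
    if (hi < lo) next
    j <- lo:hi
    out[[i]] <- data.frame(
      adduct = candidates$adduct[i], rank = candidates$rank[i],
      neutral_mass = M,
      name = compounds$name[j], formula = compounds$formula[j],
      compound_mass = masses[j],
      source = if (!is.null(compounds$source)) compounds$source[j] else NA,
      ppm_error = abs(M - masses[j]) / masses[j] * 1e6)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(adduct = character(0), rank = numeric(0),
                      neutral_mass = numeric(0), name = character(0),
                      formula = character(0), compound_mass = numeric(0),
                      source = character(0), ppm_error = numeric(0))
  }
  res[res$ppm_error <= ppm_max + 1e-9, , drop = FALSE]
}

#' Rank a feature's annotation records and assign its MRS level
#'
#' Sort key: fragmentation-confirmed matches first, then the adduct heuristic
#' rank, then ascending ppm error (with name as a final deterministic
#' tie-break). The feature's minimum-reporting-standard level is 2 if any
#' match is fragmentation-confirmed, 3 if any mass-only match exists, else 4
#' (unannotated).
#'
#' @param records a [match_database()] data.frame for one feature.
#' @param fragmentation_hits optional character vector of compound names
#'   confirmed by external in-silico fragmentation.
#' @return List: `records` (ordered, with `confirmed` and `level` columns),
#'   `level` (the feature's MRS level).
#' @export
rank_annotations <- function(records, fragmentation_hits = NULL) {
  if (!nrow(records)) {
    records$confirmed <- logical(0)
    records$level <- integer(0)
    return(list(records = records, level = 4L))
  }
  records$confirmed <- if (is.null(fragmentation_hits)) {
    FALSE
  } else {
    records$name %in% fragmentation_hits
  }
  records$level <- ifelse(records$confirmed, 2L, 3L)
  ord <- order(!records$confirmed, records$rank, records$ppm_error,
               records$name)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  list(records = records, level = if (any(records$confirmed)) 2L else 3L)
}

#' Remove blocklisted putative names
#'
#' Drops records whose compound name or formula contains any blocklist token
#' (case-sensitive fixed substring match — element tokens like `Se` must not
#' hit lowercase name fragments).
#'
#' @param records annotation records with `name` and `formula` columns.
#' @param blocklist character vector of tokens
#'   (default [load_name_blocklist()]).
#' @return The filtered records.
#' @export
filter_names <- function(records, blocklist = load_name_blocklist()) {
  if (!length(blocklist) || !nrow(records)) return(records)
  hay <- paste(records$name, records$formula)
  bad <- Reduce(`|`, lapply(blocklist, function(tok) {
    grepl(tok, hay, fixed = TRUE)
  }))
  records[!bad, , drop = FALSE]
}

#' Annotate all features of a table
#'
#' Runs the full putative-identification chain per feature: candidate
#' neutral masses, ppm-tolerance database lookup, blocklist filtering, and
#' heuristic ranking with MRS level assignment.
#'
#' @param table a `feature_table`.
#' @param compounds compound table (default packaged).
#' @param ppm_max ppm tolerance.
#' @param fragmentation_hits optional named list: feature id -> confirmed
#'   compound names.
#' @param blocklist name blocklist tokens.
#' @return List: `records` (one data.frame of all ranked records with a
#'   `feature_id` column), `levels` (named integer vector of MRS levels per
#'   feature).
#' @export
annotate_table <- function(table, compounds = load_compound_table(),
                           ppm_max = 5, fragmentation_hits = NULL,
                           blocklist = load_name_blocklist()) {
  stopifnot(inherits(table, "feature_table"))
  ids <- table$features$feature_id
  levels <- stats::setNames(integer(length(ids)), ids)
  all_rec <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    cand <- neutral_mass_candidates(table$features$mz[i])
    rec <- match_database(cand, compounds, ppm_max = ppm_max)
    rec <- filter_names(rec, blocklist)
    rk <- rank_annotations(rec, fragmentation_hits[[ids[i]]])
    levels[i] <- rk$level
    if (nrow(rk$records)) {
      all_rec[[i]] <- cbind(feature_id = ids[i], rk$records)
    }
  }
  list(records = do.call(rbind, all_rec), levels = levels)
}
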