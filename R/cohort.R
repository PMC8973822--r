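#' Read a variant annotation table
#'
#' Tab-separated table of annotated variants with columns `variant_id`,
#' `cdna_hgvs`, `protein_hgvs`, the population minor allele frequencies (in
#' percent) `maf_gnomad_nfe`, `maf_evs`, `maf_1kg` (empty = not observed),
#' `in_excluded_region` (TRUE for calls in segmental duplications, repeats or
#' homopolymer stretches) and optional predictor-score columns (PolyPhen-2,
#' SIFT, CADD — stored, never computed).
#'
#' @param path Path to the TSV file.
#' @return data.frame of variant records.
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) stop("variant table not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant_id", "cdna_hgvs", "protein_hgvs", "in_excluded_region")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("variant table lacks column(s): ", paste(miss, collapse = ", "))
  df$in_excluded_region <- as.logical(df$in_excluded_region)
  df
}

#' Rarity filter on population allele frequencies
#'
#' Keeps variants outside excluded regions whose every *available* population
#' MAF is at or below the cutoff (inclusive). A variant absent from all
#' frequency databases passes: absence is itself evidence of rarity.
#'
#' @param variants data.frame with `in_excluded_region` and one or more
#'   `maf_*` columns in percent.
#' @param maf_cutoff Rarity cutoff in percent (default 1).
#' @return The retained subset of `variants`.
#' @export
filter_rare <- function(variants, maf_cutoff = 1) {
  if (maf_cutoff <= 0 || maf_cutoff > 100) stop("maf_cutoff must be in (0, 100]")
  maf_cols <- grep("^maf_", names(variants), value = TRUE)
  keep <- !variants$in_excluded_region
  for (cc in maf_cols) {
    v <- suppressWarnings(as.numeric(variants[[cc]]))
    keep <- keep & (is.na(v) | v <= maf_cutoff)
  }
  variants[keep, , drop = FALSE]
}

#' Classify a variant from its HGVS strings
#'
#' Rule-driven classification on the cDNA/protein HGVS notation alone (no
#' transcript model is consulted): a protein consequence containing a stop
#' (`*`/`Ter`) is `ptc`; deletions, duplications and insertions are `indel`;
#' intronic offsets beyond the canonical +/-1,2 dinucleotides are `splice`
#' (offsets of 1-2 are canonical splice-site hits, grouped with `ptc`);
#' remaining substitutions with a protein change are `missense`.
#'
#' @param cdna_hgvs Character vector of cDNA HGVS strings (e.g. `"c.1859T>C"`).
#' @param protein_hgvs Matching protein HGVS strings (may be empty/`NA`).
#' @return Character vector with values in
#'   `c("missense", "indel", "splice", "ptc")`.
#' @export
classify_variant <- function(cdna_hgvs, protein_hgvs = "") {
  if (length(protein_hgvs) == 1 && length(cdna_hgvs) > 1)
    protein_hgvs <- rep(protein_hgvs, length(cdna_hgvs))
  mapply(function(cd, pr) {
    cd0 <- gsub("\\s", "", cd %||% "")
    pr0 <- gsub("\\s", "", if (is.na(pr)) "" else pr)
    if (!grepl("^c\\.", cd0)) stop("unparsable HGVS: '", cd, "'")
    if (grepl("\\*[0-9]*\\)?$|Ter", pr0) && !grepl("^p\\.\\(?\\*", pr0))
      return("ptc")
    if (grepl("del|dup|ins", cd0)) return("indel")
    m <- regmatches(cd0, regexec("^c\\.[0-9*-]+([+-])([0-9]+)", cd0))[[1]]
    if (length(m) == 3) {
      off <- as.integer(m[3])
      return(if (off <= 2) "ptc" else "splice")
    }
    if (grepl("^c\\.[0-9]+[ACGT]>[ACGT]$", cd0)) {
      if (pr0 == "" || grepl("^p\\.\\(?=", pr0)) {
        stop("substitution without protein consequence: '", cd, "'")
      }
      return("missense")
    }
    stop("unparsable HGVS: '", cd, "'")
  }, cdna_hgvs, protein_hgvs, USE.NAMES = FALSE)
}

#' Carrier frequency as a reported percentage
#'
#' The cohort frequency `100 * carriers / cohort_size`, carrying both the
#' exact value and the reporting convention used throughout: rounded half-up
#' to `digits` decimals.
#'
#' @param carriers Carrier count (0 <= carriers <= cohort_size).
#' @param cohort_size Cohort size (> 0).
#' @param digits Decimals for the reported percentage (default 2).
#' @return An object of class `carrier_frequency`: list with `carriers`,
#'   `cohort_size`, `exact_pct` and the rounded `pct`.
#' @export
carrier_frequency <- function(carriers, cohort_size, digits = 2) {
  if (cohort_size <= 0) stop("cohort_size must be > 0")
  if (carriers < 0 || carriers > cohort_size)
    stop("carriers must lie in [0, cohort_size]")
  exact <- 100 * carriers / cohort_size
  structure(list(carriers = carriers, cohort_size = cohort_size,
                 exact_pct = exact, pct = round_half_up(exact, digits)),
            class = "carrier_frequency")
}

#' @export
print.carrier_frequency <- function(x, ...) {
  cat(sprintf("%.2f%% (%d/%d)\n", x$pct, x$carriers, x$cohort_size))
  invisible(x)
}

# Two-sided Fisher exact p by the minimum-likelihood rule: sum of
# hypergeometric probabilities of all tables (at fixed margins) no more
# probable than the observed one.
fisher_p_two_sided <- function(a, b, c, d) {
  m <- a + b; n <- c + d; kk <- a + c
  support <- max(0L, kk - n):min(kk, m)
  probs <- stats::dhyper(support, m, n, kk)
  obs <- stats::dhyper(a, m, n, kk)
  min(sum(probs[probs <= obs * (1 + 1e-7)]), 1)
}

#' 2x2 contingency test for carrier counts
#'
#' Fisher's exact test (two-sided, minimum-likelihood rule) on the table
#' `rbind(c(a, b), c(c, d))` — conventionally carriers/non-carriers in
#' patients (row 1) and controls (row 2) — with the sample odds ratio
#' `ad/bc` and a Woolf logit 95% confidence interval. When any cell is zero
#' the Haldane-Anscombe 0.5 correction is applied to the odds ratio and CI
#' (flagged in the result); the p-value is always computed on the raw counts.
#'
#' @param a,b,c,d Non-negative cell counts; both row margins must be > 0.
#' @return Object of class `contingency_result`: `table`, `odds_ratio`,
#'   `ci95`, `p_two_sided`, `corrected`, `method`.
#' @export
contingency_test <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("counts must be >= 0")
  if (a + b == 0 || c + d == 0) stop("zero row margin")
  if (a + c == 0 || b + d == 0) stop("zero column margin")
  p <- fisher_p_two_sided(a, b, c, d)
  corrected <- any(cells == 0)
  cc <- if (corrected) cells + 0.5 else cells
  or <- (cc[1] * cc[4]) / (cc[2] * cc[3])
  se_log <- sqrt(sum(1 / cc))
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se_log)
  structure(list(table = matrix(c(a, b, c, d), 2, byrow = TRUE,
                                dimnames = list(c("patients", "controls"),
                                                c("carrier", "non_carrier"))),
                 odds_ratio = or, ci95 = ci, p_two_sided = p,
                 corrected = corrected,
                 method = "Fisher exact (two-sided, minimum-likelihood)"),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  print(x$table)
  cat(sprintf("OR = %.3f [%.3f, %.3f]%s, p = %.4g (%s)\n", x$odds_ratio,
              x$ci95[1], x$ci95[2],
              if (x$corrected) " (Haldane-Anscombe corrected)" else "",
              x$p_two_sided, x$method))
  invisible(x)
}

#' Count individuals carrying two or more distinct variants
#'
#' @param roster Either a named list mapping individual id to a character
#'   vector of carried variant ids, or a data.frame with columns
#'   `individual_id` and `variant_id`. Duplicate listings of the same
#'   variant in one individual collapse to one.
#' @return Integer count of multi-variant (compound) carriers.
#' @export
multi_variant_carriers <- function(roster) {
  if (is.data.frame(roster))
    roster <- split(roster$variant_id, roster$individual_id)
  if (!length(roster)) return(0L)
  sum(vapply(roster, function(v) length(unique(v)) >= 2, logical(1)))
}

#' Tally carriers per cohort and variant class
#'
#' Joins a carrier roster to a classified variant table and produces one
#' carrier table per cohort: per-class carrier counts (an individual counts
#' once per class), total carriers, mutation observations and
#' multi-variant carriers, with reported frequencies from
#' [carrier_frequency()].
#'
#' @param roster data.frame with columns `individual_id`, `cohort`
#'   (`"patients"` or `"controls"`), `variant_id`.
#' @param variants data.frame with `variant_id` and `variant_class` (or HGVS
#'   columns from which classes are derived via [classify_variant()]).
#' @param cohort_sizes Named vector, e.g. `c(patients = 1376, controls = 976)`.
#' @return data.frame of class `carrier_table`, one row per cohort x class
#'   (plus `any` and `multi_variant` rows) with counts and percentages.
#' @export
tally_carriers <- function(roster, variants, cohort_sizes) {
  bad <- !roster$cohort %in% names(cohort_sizes)
  if (any(bad))
    stop(sprintf("roster line %d: individual '%s' in unknown cohort '%s'",
                 which(bad)[1], roster$individual_id[which(bad)[1]],
                 roster$cohort[which(bad)[1]]))
  if (is.null(variants$variant_class))
    variants$variant_class <- classify_variant(variants$cdna_hgvs,
                                               variants$protein_hgvs)
  cls <- variants$variant_class[match(roster$variant_id, variants$variant_id)]
  if (anyNA(cls))
    stop("roster variant(s) missing from variant table: ",
         paste(unique(roster$variant_id[is.na(cls)]), collapse = ", "))
  roster$variant_class <- cls
  rows <- list()
  for (co in names(cohort_sizes)) {
    d <- roster[roster$cohort == co, , drop = FALSE]
    size <- cohort_sizes[[co]]
    for (cl in sort(unique(variants$variant_class))) {
      dc <- d[d$variant_class == cl, , drop = FALSE]
      cf <- carrier_frequency(length(unique(dc$individual_id)), size)
      rows[[length(rows) + 1L]] <- data.frame(
        cohort = co, class = cl, carriers = cf$carriers,
        mutations = nrow(unique(dc[c("individual_id", "variant_id")])),
        cohort_size = size, pct = cf$pct, stringsAsFactors = FALSE)
    }
    cf_any <- carrier_frequency(length(unique(d$individual_id)), size)
    rows[[length(rows) + 1L]] <- data.frame(
      cohort = co, class = "any", carriers = cf_any$carriers,
      mutations = nrow(unique(d[c("individual_id", "variant_id")])),
      cohort_size = size, pct = cf_any$pct, stringsAsFactors = FALSE)
    multi <- multi_variant_carriers(d[c("individual_id", "variant_id")])
    cf_m <- carrier_frequency(multi, size)
    rows[[length(rows) + 1L]] <- data.frame(
      cohort = co, class = "multi_variant", carriers = multi,
      mutations = NA_integer_, cohort_size = size, pct = cf_m$pct,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  class(out) <- c("carrier_table", class(out))
  out
}

#' Synthetic carrier roster matching the published Belgian tallies
#'
#' The study's individual-level roster is not public. This generator builds a
#' synthetic stand-in whose aggregate tallies match the printed cohort
#' counts: 115 rare-variant observations among 1376 patients (101 missense,
#' 10 splice, 4 indel) with 11 compound carriers (five missense+missense,
#' four missense+PTC, two missense+splice), and 59 observations among 976
#' controls (50 missense, 7 splice, 2 indel) with 5 compound carriers (four
#' missense+missense, one missense+PTC). PTC partner variants are carried on
#' the roster but sit outside the missense/indel/splice tally, as in the
#' published counts.
#'
#' @return List with `roster` (data.frame: individual_id, cohort,
#'   variant_id), `variants` (data.frame: variant_id, variant_class) and
#'   `cohort_sizes`.
#' @export
synthetic_belgian_roster <- function() {
  mk <- function(cl, n) sprintf("%s_%02d", cl, seq_len(n))
  variants <- data.frame(
    variant_id = c(mk("missense", 60), mk("splice", 9), mk("indel", 6),
                   mk("ptc", 5)),
    variant_class = rep(c("missense", "splice", "indel", "ptc"),
                        c(60, 9, 6, 5)),
    stringsAsFactors = FALSE)
  pick <- function(cl, i) sprintf("%s_%02d", cl, (i - 1) %% switch(
    cl, missense = 60, splice = 9, indel = 6, ptc = 5) + 1)
  build <- function(cohort, n_missense, n_splice, n_indel, pairs) {
    # `pairs`: list of c(class1, class2) for each compound carrier; every
    # compound carrier's missense observation counts toward the class totals
    rows <- list(); idx <- 1L; used <- c(missense = 0L, splice = 0L, indel = 0L,
                                         ptc = 0L)
    add <- function(id, cl) {
      used[cl] <<- used[cl] + 1L
      rows[[length(rows) + 1L]] <<- data.frame(
        individual_id = id, cohort = cohort, variant_id = pick(cl, used[cl]),
        stringsAsFactors = FALSE)
    }
    for (p in pairs) {
      id <- sprintf("%s_%03d", cohort, idx); idx <- idx + 1L
      # ensure the two variants differ even within one class
      add(id, p[1]); add(id, p[2])
    }
    counted <- table(factor(unlist(pairs), levels = names(used)))
    for (cl in c("missense", "splice", "indel")) {
      target <- switch(cl, missense = n_missense, splice = n_splice,
                       indel = n_indel)
      for (i in seq_len(target - counted[[cl]])) {
        id <- sprintf("%s_%03d", cohort, idx); idx <- idx + 1L
        add(id, cl)
      }
    }
    do.call(rbind, c(rows, make.row.names = FALSE))
  }
  patient_pairs <- c(rep(list(c("missense", "missense")), 5),
                     rep(list(c("missense", "ptc")), 4),
                     rep(list(c("missense", "splice")), 2))
  control_pairs <- c(rep(list(c("missense", "missense")), 4),
                     list(c("missense", "ptc")))
  roster <- rbind(build("patients", 101, 10, 4, patient_pairs),
                  build("controls", 50, 7, 2, control_pairs))
  list(roster = roster, variants = variants,
       cohort_sizes = c(patients = 1376, controls = 976))
}
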