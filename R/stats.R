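#' Per-group descriptive summaries
#'
#' One row per (genotype, comarker): sample size, mean, SD, median, quartiles
#' and range of the per-cell Pearson values. Quartiles use linear
#' interpolation between order statistics (the type-7 rule).
#'
#' @param records A `coloc_records` data.frame from [measure_dataset()], or
#'   any data.frame with columns genotype_label, comarker, pearson_r.
#' @return data.frame with columns genotype_label, comarker, n, mean, sd,
#'   median, q1, q3, min, max.
#' @export
summarize_groups <- function(records) {
  if (!nrow(records)) {
    return(data.frame(genotype_label = character(0), comarker = character(0),
                      n = integer(0), mean = numeric(0), sd = numeric(0),
                      median = numeric(0), q1 = numeric(0), q3 = numeric(0),
                      min = numeric(0), max = numeric(0), stringsAsFactors = FALSE))
  }
  key <- interaction(records$genotype_label, records$comarker, drop = TRUE)
  rows <- lapply(split(records, key), function(d) {
    x <- d$pearson_r
    q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(genotype_label = d$genotype_label[1], comarker = d$comarker[1],
               n = length(x), mean = mean(x),
               sd = if (length(x) > 1) sd(x) else NA_real_,
               median = q[2], q1 = q[1], q3 = q[3],
               min = min(x), max = max(x), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out[order(out$comarker, out$genotype_label), , drop = FALSE]
}

# Coerce the flexible group inputs (named list of numeric vectors, or
# value/group vectors, or a formula) into a named list of samples.
as_sample_list <- function(x, g = NULL, data = NULL) {
  if (inherits(x, "formula")) {
    mf <- stats::model.frame(x, data = data)
    return(split(mf[[1]], mf[[2]]))
  }
  if (is.list(x)) {
    if (is.null(names(x))) names(x) <- paste0("group", seq_along(x))
    return(x)
  }
  if (!is.null(g)) return(split(as.numeric(x), g))
  stop("supply a named list of samples, a formula, or (values, groups)")
}

#' Welch heteroscedastic one-way ANOVA
#'
#' Omnibus test for equality of group means without assuming equal
#' variances. With weights \eqn{w_i = n_i / s_i^2}, \eqn{W = \sum w_i} and
#' weighted grand mean \eqn{\bar x_w}, the statistic is
#' \deqn{F = \frac{\sum w_i (\bar x_i - \bar x_w)^2 / (k - 1)}
#'            {1 + \frac{2(k-2)}{k^2 - 1} \Lambda}, \quad
#'   \Lambda = \sum \frac{(1 - w_i / W)^2}{n_i - 1},}
#' referred to an F distribution with \eqn{k - 1} and
#' \eqn{(k^2 - 1) / (3 \Lambda)} degrees of freedom.
#'
#' @param x A named list of numeric samples, a formula `values ~ group`, or a
#'   numeric vector (with `g` giving group membership).
#' @param g Optional grouping vector when `x` is numeric.
#' @param data Optional data.frame for the formula interface.
#' @return An object of class `welch_anova` with elements `F`, `df1`, `df2`,
#'   `p.value`, `k`, `W`, and per-group `means`, `vars`, `ns`, `weights`.
#' @export
welch_anova <- function(x, g = NULL, data = NULL) {
  samples <- as_sample_list(x, g, data)
  k <- length(samples)
  if (k < 2) stop("need at least 2 groups")
  ns <- vapply(samples, length, integer(1))
  if (any(ns < 2)) stop("each group needs at least 2 observations: ",
                        paste(names(samples)[ns < 2], collapse = ", "))
  vars <- vapply(samples, var, numeric(1))
  if (any(vars <= 0))
    stop("zero within-group variance in group(s): ",
         paste(names(samples)[vars <= 0], collapse = ", "))
  means <- vapply(samples, mean, numeric(1))
  w <- ns / vars
  W <- sum(w)
  xw <- sum(w * means) / W
  lambda <- sum((1 - w / W)^2 / (ns - 1))
  df1 <- k - 1
  df2 <- (k^2 - 1) / (3 * lambda)
  F <- sum(w * (means - xw)^2) / df1 / (1 + 2 * (k - 2) / (k^2 - 1) * lambda)
  structure(list(F = F, df1 = df1, df2 = df2,
                 p.value = pf(F, df1, df2, lower.tail = FALSE),
                 k = k, W = W, means = means, vars = vars, ns = ns, weights = w),
            class = "welch_anova")
}

#' @export
print.welch_anova <- function(x, ...) {
  cat("Welch heteroscedastic one-way ANOVA\n")
  cat(sprintf("  F = %.4f on %d and %.2f df, p = %.4g (k = %d groups)\n",
              x$F, x$df1, x$df2, x$p.value, x$k))
  invisible(x)
}

p_stars <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("***", "**", "*", "ns"), right = FALSE)
}

#' Games-Howell pairwise post-hoc comparisons
#'
#' Pairwise comparisons of group means under unequal variances and sizes.
#' For groups i, j: \eqn{se = \sqrt{s_i^2/n_i + s_j^2/n_j}},
#' \eqn{t = |\bar x_i - \bar x_j| / se}, Welch-Satterthwaite degrees of
#' freedom, and \eqn{q = \sqrt{2}\,t} referred to the studentized range
#' distribution with `k` groups (the full group count, so the familywise
#' correction spans all plotted comparisons even when only the versus-
#' reference subset is reported).
#'
#' @inheritParams welch_anova
#' @param reference A group name: only comparisons of every other group
#'   against it are returned. `NULL` (or `"all-pairs"`) returns all pairs.
#' @return A data.frame of class `games_howell` with columns group_i,
#'   group_j, mean_diff (group_j minus group_i), se, t, df, q, p_adj,
#'   stars.
#' @export
games_howell <- function(x, g = NULL, data = NULL, reference = NULL) {
  samples <- as_sample_list(x, g, data)
  k <- length(samples)
  if (k < 2) stop("need at least 2 groups")
  ns <- vapply(samples, length, integer(1))
  if (any(ns < 2)) stop("each group needs at least 2 observations: ",
                        paste(names(samples)[ns < 2], collapse = ", "))
  vars <- vapply(samples, var, numeric(1))
  if (any(vars <= 0))
    stop("zero within-group variance in group(s): ",
         paste(names(samples)[vars <= 0], collapse = ", "))
  means <- vapply(samples, mean, numeric(1))
  nm <- names(samples)
  if (!is.null(reference) && identical(reference, "all-pairs")) reference <- NULL
  if (!is.null(reference) && !reference %in% nm)
    stop(sprintf("reference group '%s' not present", reference))
  pairs <- if (is.null(reference)) {
    utils::combn(nm, 2, simplify = FALSE)
  } else {
    lapply(setdiff(nm, reference), function(o) c(reference, o))
  }
  rows <- lapply(pairs, function(pr) {
    i <- pr[1]; j <- pr[2]
    vi <- vars[i] / ns[i]; vj <- vars[j] / ns[j]
    se <- sqrt(vi + vj)
    tstat <- abs(means[i] - means[j]) / se
    df <- (vi + vj)^2 / (vi^2 / (ns[i] - 1) + vj^2 / (ns[j] - 1))
    q <- sqrt(2) * tstat
    p <- ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    data.frame(group_i = i, group_j = j, mean_diff = means[j] - means[i],
               se = se, t = tstat, df = df, q = q, p_adj = p,
               stars = as.character(p_stars(p)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  class(out) <- c("games_howell", class(out))
  attr(out, "k") <- k
  out
}

#' Compare every genotype to the wild type
#'
#' For each co-marker: the omnibus [welch_anova()] over all genotypes,
#' followed by [games_howell()] comparisons of every genotype against the
#' wild-type reference, with significance stars at 0.05 / 0.01 / 0.001.
#'
#' @param records A `coloc_records` data.frame (per-cell observations).
#' @param wt_label Reference genotype label (default `"WT"`).
#' @param min_cells Minimum per-genotype cell count (default 30); genotypes
#'   below it trigger an error unless `enforce_min = FALSE`.
#' @param enforce_min Set `FALSE` to analyse under-powered groups anyway.
#' @return An object of class `coloc_wt_test`: per co-marker, a list with
#'   `omnibus` (`welch_anova`) and `posthoc` (`games_howell`).
#' @export
compare_to_wt <- function(records, wt_label = "WT", min_cells = 30,
                          enforce_min = TRUE) {
  if (!wt_label %in% records$genotype_label)
    stop(sprintf("wt_label '%s' not present in records", wt_label))
  out <- list()
  for (cm in sort(unique(records$comarker))) {
    d <- records[records$comarker == cm, , drop = FALSE]
    samples <- split(d$pearson_r, d$genotype_label)
    if (length(samples) < 2)
      stop(sprintf("comarker %s: need at least 2 genotypes", cm))
    ns <- vapply(samples, length, integer(1))
    if (enforce_min && any(ns < min_cells))
      stop(sprintf("comarker %s: genotype(s) below %d cells: %s", cm, min_cells,
                   paste(sprintf("%s (n=%d)", names(ns)[ns < min_cells],
                                 ns[ns < min_cells]), collapse = ", ")))
    out[[cm]] <- list(omnibus = welch_anova(samples),
                      posthoc = games_howell(samples, reference = wt_label))
  }
  structure(list(comarkers = out, wt_label = wt_label), class = "coloc_wt_test")
}

#' @export
print.coloc_wt_test <- function(x, digits = 4, ...) {
  for (cm in names(x$comarkers)) {
    res <- x$comarkers[[cm]]
    cat(sprintf("== Co-marker %s ==\n", cm))
    print(res$omnibus)
    ph <- res$posthoc
    cat(sprintf("  Games-Howell vs %s:\n", x$wt_label))
    for (i in seq_len(nrow(ph)))
      cat(sprintf("    %-12s diff = %+.*f  p_adj = %.4g %s\n", ph$group_j[i],
                  digits, ph$mean_diff[i], ph$p_adj[i], ph$stars[i]))
  }
  invisible(x)
}

#' @export
summary.coloc_wt_test <- function(object, ...) {
  rows <- lapply(names(object$comarkers), function(cm) {
    res <- object$comarkers[[cm]]
    cbind(comarker = cm, res$posthoc,
          omnibus_F = res$omnibus$F, omnibus_p = res$omnibus$p.value)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
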