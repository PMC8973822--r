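#' Default genotype panel for the synthetic study
#'
#' Membrane fractions for a wild-type reference, ten mislocalizing
#' (ER-retained) missense mutants and four benign/protective variants. The
#' mutant labels follow protein HGVS convention.
#'
#' @return Named numeric vector mapping genotype label to `alpha`.
#' @export
default_genotype_alphas <- function() {
  damaging <- c("p.L620P", "p.G826R", "p.A845V", "p.R880Q", "p.R989H",
                "p.G1731S", "p.G1820S", "p.R1932C", "p.P1952R", "p.F2100S")
  benign <- c("p.E188G", "p.G215S", "p.R1349Q", "p.G1527A")
  c(WT = 0.8, stats::setNames(rep(0.1, length(damaging)), damaging),
    stats::setNames(rep(0.8, length(benign)), benign))
}

#' Assemble a pipeline run configuration
#'
#' @param genotype_alphas Named vector mapping genotype label to membrane
#'   fraction `alpha`; must contain `wt_label`.
#' @param images_per_genotype Fields of view per genotype and co-marker.
#' @param comarkers Co-marker channels to simulate and analyse.
#' @param scene Named list of [scene_spec()] argument overrides applied to
#'   every genotype (e.g. `list(n_cells = 3)`).
#' @param segmentation A [segmentation_params()] object.
#' @param wt_label Reference genotype.
#' @param min_cells Minimum cells per genotype for inference (default 30).
#' @param base_seed Integer base seed for the whole run.
#' @param output_dir Optional directory for TSV/JSON outputs.
#' @return Object of class `run_config`.
#' @export
run_config <- function(genotype_alphas = default_genotype_alphas(),
                       images_per_genotype = 20,
                       comarkers = c("PM", "ER"),
                       scene = list(),
                       segmentation = segmentation_params(),
                       wt_label = "WT", min_cells = 30,
                       base_seed = 1L, output_dir = NULL) {
  if (!wt_label %in% names(genotype_alphas))
    stop(sprintf("wt_label '%s' absent from genotype_alphas", wt_label))
  if (any(genotype_alphas < 0 | genotype_alphas > 1))
    stop("all alphas must lie in [0, 1]")
  stopifnot(all(comarkers %in% c("PM", "ER")))
  structure(list(genotype_alphas = genotype_alphas,
                 images_per_genotype = images_per_genotype,
                 comarkers = comarkers, scene = scene,
                 segmentation = segmentation, wt_label = wt_label,
                 min_cells = min_cells, base_seed = as.integer(base_seed),
                 output_dir = output_dir),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised blocks: `synthgen` (scene_spec overrides plus `alpha_map`),
#' `segmentation`, `stats` (`wt_label`, `min_cells`), `run`
#' (`images_per_genotype`, `comarkers`, `base_seed`, `output_dir`).
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sg <- y$synthgen %||% list()
  alphas <- if (!is.null(sg$alpha_map)) unlist(sg$alpha_map) else
    default_genotype_alphas()
  sg$alpha_map <- NULL
  seg <- do.call(segmentation_params, y$segmentation %||% list())
  run <- y$run %||% list()
  st <- y$stats %||% list()
  run_config(genotype_alphas = alphas,
             images_per_genotype = run$images_per_genotype %||% 20,
             comarkers = unlist(run$comarkers) %||% c("PM", "ER"),
             scene = sg, segmentation = seg,
             wt_label = st$wt_label %||% "WT",
             min_cells = st$min_cells %||% 30,
             base_seed = run$base_seed %||% 1L,
             output_dir = run$output_dir)
}

config_fingerprint <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the imaging workflow end to end
#'
#' Simulate (or ingest) scenes, segment each protein channel, measure
#' per-cell colocalization against each co-marker, and compare every
#' genotype to the wild type. Fully reproducible from `(config, base_seed)`.
#'
#' @param config A [run_config()].
#' @param scenes Optional pre-built named list of `coloc_scene` objects (one
#'   list per co-marker, named by co-marker); when supplied, simulation is
#'   skipped and these are analysed instead.
#' @param mask_overrides Optional named list (scene id -> `label_mask` or
#'   label matrix) replacing the automatic segmentation for those scenes.
#' @return Object of class `run_report`: per-stage counts, group summaries,
#'   per-co-marker `coloc_wt_test` results, the per-cell records, and the
#'   config fingerprint.
#' @export
run_imaging_pipeline <- function(config, scenes = NULL, mask_overrides = NULL) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  all_records <- list(); n_scenes <- 0L; n_seg <- 0L; n_drop <- 0L
  for (ci in seq_along(config$comarkers)) {
    cm <- config$comarkers[ci]
    if (is.null(scenes)) {
      specs <- lapply(names(config$genotype_alphas), function(gt) {
        args <- config$scene
        args$alpha <- config$genotype_alphas[[gt]]
        args$comarker <- cm
        args$genotype_label <- gt
        do.call(scene_spec, args)
      })
      seed_cm <- as.integer((as.numeric(config$base_seed) + ci * 50021) %% 2147483647)
      ds <- generate_dataset(specs, config$images_per_genotype, base_seed = seed_cm)
      sc_list <- ds$scenes
    } else {
      sc_list <- scenes[[cm]]
      if (is.null(sc_list)) stop(sprintf("no scenes supplied for comarker %s", cm))
    }
    n_scenes <- n_scenes + length(sc_list)
    masks <- lapply(sc_list, function(s)
      extract_rois(s$channels$protein, config$segmentation))
    if (!is.null(mask_overrides)) {
      for (id in intersect(names(mask_overrides), names(masks)))
        masks[[id]] <- apply_mask_override(masks[[id]], mask_overrides[[id]])
    }
    n_seg <- n_seg + sum(vapply(masks, function(m) nrow(m$table), integer(1)))
    rec <- measure_dataset(sc_list, masks, config$segmentation)
    n_drop <- n_drop + NROW(attr(rec, "dropped"))
    all_records[[cm]] <- rec
  }
  records <- do.call(rbind, c(lapply(all_records, as.data.frame),
                              make.row.names = FALSE))
  test <- compare_to_wt(records, wt_label = config$wt_label,
                        min_cells = config$min_cells)
  report <- structure(list(
    counts = list(scenes = n_scenes, cells_segmented = n_seg,
                  cells_measured = nrow(records), cells_dropped = n_drop),
    summaries = summarize_groups(records),
    test = test, records = records,
    fingerprint = config_fingerprint(config),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "run_report")
  if (!is.null(config$output_dir)) write_run_report(report, config$output_dir)
  report
}

write_run_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(report$records, file.path(dir, "measurements.tsv"))
  write_tsv(report$summaries, file.path(dir, "summary.tsv"))
  posthoc <- summary(report$test)
  write_tsv(posthoc, file.path(dir, "posthoc.tsv"))
  omnibus <- do.call(rbind, lapply(names(report$test$comarkers), function(cm) {
    o <- report$test$comarkers[[cm]]$omnibus
    data.frame(comarker = cm, F = o$F, df1 = o$df1, df2 = o$df2,
               p = o$p.value, k = o$k, stringsAsFactors = FALSE)
  }))
  write_tsv(omnibus, file.path(dir, "omnibus.tsv"))
  jsonlite::write_json(
    list(counts = report$counts, fingerprint = report$fingerprint,
         elapsed_s = report$elapsed_s,
         box_summary = report$summaries),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d scenes, %d cells segmented, %d measured (%d dropped); fingerprint %s\n",
              x$counts$scenes, x$counts$cells_segmented, x$counts$cells_measured,
              x$counts$cells_dropped, substr(x$fingerprint, 1, 8)))
  print(x$test)
  invisible(x)
}

#' Run the rare-variant cohort workflow
#'
#' Filter the annotated variants for rarity, classify them from HGVS,
#' tally carriers per cohort and class from the roster, and test
#' compound-carrier enrichment between cohorts with Fisher's exact test.
#'
#' @param variants data.frame (or TSV path) of variant annotations; see
#'   [read_variant_table()].
#' @param roster data.frame (or TSV path) with columns individual_id,
#'   cohort, variant_id.
#' @param cohort_sizes Named vector of cohort sizes, e.g.
#'   `c(patients = 1376, controls = 976)`.
#' @param maf_cutoff Rarity cutoff in percent (default 1).
#' @param output_dir Optional directory for the carrier table TSV and the
#'   contingency JSON.
#' @return Object of class `cohort_report`: `variants_rare`, `tally`,
#'   `contingency` (compound carriers, patients vs controls) and counts.
#' @export
run_cohort_analysis <- function(variants, roster, cohort_sizes,
                                maf_cutoff = 1, output_dir = NULL) {
  if (is.character(variants)) variants <- read_variant_table(variants)
  if (is.character(roster)) roster <- read_roster(roster)
  rare <- filter_rare(variants, maf_cutoff)
  if (is.null(rare$variant_class))
    rare$variant_class <- classify_variant(rare$cdna_hgvs, rare$protein_hgvs)
  roster_rare <- roster[roster$variant_id %in% rare$variant_id, , drop = FALSE]
  tally <- tally_carriers(roster_rare, rare, cohort_sizes)
  multi <- tally[tally$class == "multi_variant", ]
  mp <- multi$carriers[multi$cohort == "patients"]
  mc <- multi$carriers[multi$cohort == "controls"]
  contingency <- if (length(mp) && length(mc))
    contingency_test(mp, cohort_sizes[["patients"]] - mp,
                     mc, cohort_sizes[["controls"]] - mc)
  report <- structure(list(
    variants_total = nrow(variants), variants_rare = rare,
    tally = tally, contingency = contingency
  ), class = "cohort_report")
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(tally, file.path(output_dir, "carrier_table.tsv"))
    if (!is.null(contingency))
      jsonlite::write_json(
        list(table = contingency$table, odds_ratio = contingency$odds_ratio,
             ci95 = contingency$ci95, p_two_sided = contingency$p_two_sided,
             method = contingency$method),
        file.path(output_dir, "contingency.json"), digits = NA)
  }
  report
}

#' Read a carrier roster TSV
#' @param path TSV with columns individual_id, cohort, variant_id.
#' @return data.frame.
#' @export
read_roster <- function(path) {
  if (!file.exists(path)) stop("roster not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "cohort", "variant_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("roster lacks column(s): ", paste(miss, collapse = ", "))
  }
  bad <- which(is.na(df$individual_id) | !nzchar(df$individual_id) |
                 is.na(df$variant_id) | !nzchar(df$variant_id))
  if (length(bad))
    stop(sprintf("roster line %d: empty individual_id or variant_id", bad[1] + 1L))
  df
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d variants in, %d rare retained\n",
              x$variants_total, nrow(x$variants_rare)))
  print(as.data.frame(x$tally))
  if (!is.null(x$contingency)) {
    cat("Compound-carrier enrichment (patients vs controls):\n")
    print(x$contingency)
  }
  invisible(x)
}
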