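# CSV writer with floats serialized at 12 significant digits for
# reproducible diffs.
write_csv12 <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      df[[j]] <- ifelse(is.na(df[[j]]), NA, sprintf("%.12g", df[[j]]))
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

default_pipeline_params <- function() {
  list(trait = "digital_biomass", outlier_threshold_sd = 3.5,
       maf_min = 0.05, missing_max = 0.05, fdr_q = 0.1, loess_span = 0.3,
       unlinked_cM = 50, detection_window_cM = 8, scan_mode = "null_varcomp_reuse")
}

#' Run the full longitudinal GWAS pipeline
#'
#' Sequences the analysis stages end to end: outlier screening, per- and
#' across-experiment BLUEs, variance components and heritability per day,
#' logistic growth fits with inflection points, LD decay with background
#' threshold and extent, kinship, per-day mixed-model scans with FDR,
#' per-day variance explained for significant markers, QTL trajectories,
#' and favorable-allele stacking. Each stage writes a CSV/JSON artifact
#' into `out_dir` and logs one line with record counts; a provenance
#' record (config echo, seed, package version) is always written.
#'
#' @param config A named list, or path to a YAML file, with elements:
#'   `inputs` (paths `genotypes`, `map`, `phenotypes`) or `simulate`
#'   (arguments for [simulate_genotypes()] plus optional `phenotypes`
#'   arguments for [simulate_growth_phenotypes()]); optional `params`
#'   overriding [scan/filter defaults]; `out_dir`; `seed`. Unknown
#'   top-level keys are rejected.
#' @return Invisibly, a list of the main stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("inputs", "simulate", "params", "out_dir", "seed")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  out_dir <- config$out_dir %||% stop("config needs an out_dir", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  params <- utils::modifyList(default_pipeline_params(), config$params %||% list())
  stage <- function(name, ...) message(sprintf("[%s] %s", name, paste0(...)))

  jsonlite::write_json(
    list(config = config, seed = seed,
         package_version = as.character(utils::packageVersion("growthgwas")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, null = "null"
  )

  # --- inputs -----------------------------------------------------------
  if (!is.null(config$inputs)) {
    panel <- read_genotypes(config$inputs$genotypes)
    map <- read_genetic_map(config$inputs$map)
    records <- read_phenotypes(config$inputs$phenotypes)
    stage("inputs", nrow(panel$calls), " genotypes, ", ncol(panel$calls),
          " markers, ", nrow(records), " phenotype records read")
  } else if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    ph_args <- sim_args$phenotypes %||% list()
    sim_args$phenotypes <- NULL
    sim <- do.call(simulate_genotypes, c(sim_args, list(seed = seed)))
    panel <- sim$panel; map <- sim$map
    records <- do.call(simulate_growth_phenotypes,
                       c(list(panel = panel, seed = seed + 1L), ph_args))
    stage("simulate", nrow(panel$calls), " genotypes, ", ncol(panel$calls),
          " markers, ", nrow(records), " phenotype records generated")
  } else stop("config needs 'inputs' or 'simulate'", call. = FALSE)

  trait <- params$trait

  # --- phenotype pipeline ----------------------------------------------
  records <- detect_outliers(records, threshold_sd = params$outlier_threshold_sd)
  stage("outliers", sum(records$outlier), " of ", nrow(records), " records flagged")
  write_csv12(records, file.path(out_dir, "phenotypes_flagged.csv"))

  step1 <- compute_blues_step1(records)
  step2 <- compute_blues_step2(step1)
  stage("blues", nrow(step1), " step-1 and ", nrow(step2), " step-2 BLUEs")
  write_csv12(step1, file.path(out_dir, "blues_step1.csv"))
  write_csv12(step2, file.path(out_dir, "blues_step2.csv"))

  h2 <- heritability_by_day(records, trait)
  stage("heritability", nrow(h2), " trait-days; H2 range ",
        sprintf("%.2f-%.2f", min(h2$H2), max(h2$H2)))
  write_csv12(h2, file.path(out_dir, "heritability.csv"))

  fits <- fit_growth(step1[step1$trait == trait, ], trait = trait)
  stage("growth", sum(fits$converged), " of ", nrow(fits), " logistic fits converged")
  write_csv12(fits, file.path(out_dir, "logistic_fits.csv"))

  # --- genotypes --------------------------------------------------------
  panel_f <- filter_markers(panel, params$maf_min, params$missing_max)
  stage("filter", ncol(panel_f$calls), " of ", ncol(panel$calls),
        " markers pass MAF/missingness")
  ld <- tryCatch(
    ld_decay(panel_f, map, loess_span = params$loess_span,
             unlinked_cM = params$unlinked_cM, seed = seed),
    error = function(e) { warning("LD stage skipped: ", conditionMessage(e)); NULL }
  )
  if (!is.null(ld)) {
    stage("ld", nrow(ld$pairs), " pairs; threshold ",
          sprintf("%.4f", ld$threshold_r2), "; extent ",
          sprintf("%.2f cM", ld$extent_cM))
    write_csv12(ld$pairs, file.path(out_dir, "ld_pairs.csv"))
    jsonlite::write_json(
      list(threshold_r2 = ld$threshold_r2, extent_cM = ld$extent_cM),
      file.path(out_dir, "ld_summary.json"), auto_unbox = TRUE, digits = NA)
  }
  K <- compute_kinship(panel_f)
  stage("kinship", nrow(K$K), " genotypes from ", K$n_markers, " markers")
  utils::write.table(K$K, file.path(out_dir, "kinship.tsv"), sep = "\t",
                     quote = FALSE)

  # --- GWAS -------------------------------------------------------------
  scans <- scan_days(step1, panel_f, K, trait = trait, q = params$fdr_q,
                     mode = params$scan_mode)
  stage("gwas", length(unique(scans$day)), " days scanned; ",
        sum(scans$significant), " significant marker-days")

  # per-day variance explained for significant markers
  h2_lookup <- stats::setNames(h2$H2, h2$day)
  scans$var_explained <- NA_real_
  for (d in unique(scans$day[scans$significant])) {
    sig_m <- scans$marker_id[scans$day == d & scans$significant]
    bl <- step2[step2$trait == trait & step2$day == d, ]
    ve <- variance_explained(bl, panel_f, sig_m, h2 = unname(h2_lookup[as.character(d)]))
    rows <- match(paste(sig_m, d), paste(scans$marker_id, scans$day))
    scans$var_explained[rows] <- ve$individual$var_explained
  }
  write_csv12(scans, file.path(out_dir, "gwas_scans.csv"))

  traj <- qtl_trajectories(scans)
  stage("trajectories", nrow(traj), " QTL with >= 1 significant day")
  write_csv12(dplyr::select(traj, -"series"),
              file.path(out_dir, "qtl_trajectories.csv"))

  # --- stacking ---------------------------------------------------------
  stacking <- NULL
  if (nrow(traj) > 0) {
    std <- standardize_daily_biomass(step2[step2$trait == trait, ])
    fav <- assign_favorable_alleles(scans,
                                    step2[step2$trait == trait, ],
                                    panel_f, traj$marker_id)
    early <- traj$marker_id[traj$pattern == "decreasing"]
    late <- traj$marker_id[traj$pattern %in% c("increasing", "peaked")]
    subsets <- list(all = traj$marker_id)
    if (length(early)) subsets$early <- early
    if (length(late)) subsets$late <- late
    if (length(early) && length(late)) subsets$early_late <- union(early, late)
    stacking <- stacking_trajectories(std, panel_f, fav, subsets)
    stage("stacking", nrow(stacking$group_means), " group-day means over ",
          length(subsets), " subsets")
    write_csv12(stacking$membership, file.path(out_dir, "stacking_membership.csv"))
    write_csv12(stacking$group_means, file.path(out_dir, "stacking_trajectories.csv"))
  } else {
    stage("stacking", "skipped: no significant QTL")
    write_csv12(tibble::tibble(subset = character(), genotype = character(),
                               group = character()),
                file.path(out_dir, "stacking_membership.csv"))
  }

  invisible(list(panel = panel_f, map = map, records = records, step1 = step1,
                 step2 = step2, heritability = h2, fits = fits, ld = ld,
                 kinship = K, scans = scans, trajectories = traj,
                 stacking = stacking))
}
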