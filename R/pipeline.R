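# End-to-end pipeline driver and run configuration.

#' Validate a run configuration
#'
#' @param config Named list (typically from a YAML file): input paths
#'   (`genotypes`, `map`, `crosses`, `phenotypes`, `ec_daily`, optional
#'   `grid`), `trait`, optional `subpopulation`, `alpha` (default 0.05),
#'   `window` cM (default 20), `min_seg` (default 10), `k_ec` (default 5),
#'   `seed` (default 1), `out_dir`.
#' @return The completed configuration (defaults filled in); errors on
#'   invalid values or missing input files.
#' @export
run_config <- function(config) {
  defaults <- list(alpha = 0.05, window = 20, min_seg = 10, k_ec = 5,
                   seed = 1L, subpopulation = NULL, grid = NULL,
                   trait = NULL)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  stopifnot(config$alpha > 0, config$alpha < 1, config$window > 0,
            config$min_seg >= 1, config$k_ec >= 1)
  needed <- c("genotypes", "map", "crosses", "phenotypes", "ec_daily")
  for (nm in needed) {
    if (is.null(config[[nm]])) stop("config lacks input path '", nm, "'")
    if (!file.exists(config[[nm]])) {
      stop("input file for '", nm, "' not found: ", config[[nm]])
    }
  }
  if (!is.null(config$grid) && !file.exists(config$grid)) {
    stop("projection grid not found: ", config$grid)
  }
  if (is.null(config$out_dir)) stop("config lacks 'out_dir'")
  config
}

#' Run the full QTLxEC analysis pipeline
#'
#' Orders the complete sequence: within-environment BLUEs, EC window
#' selection, parental dosage inference, SIM scan, cofactor selection, CIM
#' scan, final QTL selection with R-squared, main/QEI decomposition
#' (model 3), EC sensitivities (model 4), unique-QTL grouping, and (when a
#' grid is configured) projection of allelic effects. Every stage writes a
#' CSV into `out_dir` and the run ends with a JSON manifest recording the
#' resolved configuration, seed, and per-stage row counts and checksums,
#' so identical configurations reproduce identical outputs.
#'
#' @param config A configuration list (see [run_config()]) or the path to
#'   a YAML file holding one.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- run_config(config)
  set.seed(as.integer(config$seed))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = config[setdiff(names(config), "out_dir")],
                   package_version = as.character(
                     utils::packageVersion("mppqtlx")),
                   stages = list())
  stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    res
  }
  emit <- function(name, df, file) {
    path <- file.path(config$out_dir, file)
    utils::write.csv(df, path, row.names = FALSE)
    manifest$stages[[name]] <<- list(
      file = file, rows = nrow(df),
      md5 = unname(tools::md5sum(path)))
    invisible(path)
  }

  map <- stage("inputs", function() read_genetic_map(config$map))
  geno <- read_genotypes(config$genotypes)
  crosses <- read_crosses(config$crosses)
  plots <- read_phenotypes(config$phenotypes)
  ec_daily <- read_ec_daily(config$ec_daily)
  subpop <- config$subpopulation

  blues <- stage("blues", function()
    fit_env_blues(plots, trait = config$trait))
  emit("blues", blues, "blues.csv")

  vc <- stage("h2", function()
    estimate_variance_components(plots, trait = config$trait))
  emit("h2", vc, "variance_components.csv")

  ecsel <- stage("ecselect", function() {
    em <- env_means(blues)
    tab <- ec_trait_scan(em, ec_daily)
    select_top_ecs(tab, ec_daily, k = config$k_ec)
  })
  emit("ecselect", as.data.frame(ecsel), "ec_selection.csv")

  dosage <- stage("dosage", function() {
    progeny <- crosses$genotype
    parents <- setdiff(rownames(geno), progeny)
    infer_parental_dosage(geno[progeny, , drop = FALSE],
                          geno[parents, , drop = FALSE], crosses, map)
  })

  det <- stage("scan", function()
    qtl_detect(blues, dosage, trait = config$trait,
               subpopulation = subpop, alpha = config$alpha,
               window = config$window, min_seg = config$min_seg))
  emit("sim_profile", det$sim, "profile_sim.csv")
  emit("cim_profile", det$cim, "profile_cim.csv")
  emit("qtl", det$qtl, "qtl.csv")

  if (nrow(det$qtl) > 0L) {
    m3 <- stage("model3", function()
      fit_model3(blues, dosage, det$qtl$marker, trait = config$trait,
                 subpopulation = subpop, min_seg = config$min_seg,
                 alpha_level = config$alpha))
    emit("model3", m3$table, "allelic_effects.csv")

    qei <- m3$table[m3$table$class == "QEI", c("qtl", "parent")]
    sens <- stage("model4", function() {
      if (nrow(qei) == 0L) {
        return(structure(data.frame(), class = c("ec_sensitivity",
                                                 "data.frame")))
      }
      fit_model4(blues, dosage, det$qtl$marker, qei,
                 attr(ecsel, "ec_values"), trait = config$trait,
                 subpopulation = subpop, min_seg = config$min_seg)
    })
    emit("model4", as.data.frame(sens), "ec_sensitivity.csv")

    groups <- stage("group", function() {
      q <- det$qtl[, c("chr", "pos", "marker")]
      q$trait <- if (is.null(config$trait)) "trait" else config$trait
      group_unique_qtl(q, max_span = 10)
    })
    emit("group", groups, "unique_qtl.csv")

    if (!is.null(config$grid) && nrow(sens) > 0L) {
      proj <- stage("project", function() {
        grid <- read_projection_grid(config$grid)
        keep <- sens[!is.na(sens$p_value) &
                       sens$p_value < config$alpha, , drop = FALSE]
        if (nrow(keep) == 0L) keep <- sens
        project_effects(keep, grid)
      })
      emit("project", proj, "projection.csv")
    }
  }

  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
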