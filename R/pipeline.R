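# Configuration-driven orchestration: one root seed fans out into named
# substreams so each stage is independently reproducible, every output TSV is
# deterministic, and a JSON manifest records versions, seeds and parameters
# alongside the results.

#' Build the demonstration study configuration
#'
#' A fully synthetic study mirroring the emulated design: a 4-arm cohort
#' (13/17/17/15 animals), a 6-reference / 7-target qPCR plate, a
#' two-condition expression bundle with planted repressed gene sets among a
#' 67-set collection, and two grids of rendered vessels with different
#' dilated-vessel prevalence. Sizes are kept modest so the demonstration runs
#' in seconds.
#'
#' @param seed root seed; every stage derives its own substream from it.
#' @return A config list consumable by [run_study()].
#' @export
demo_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    cohort = list(generate = TRUE, weight_noise_cv = 0.3,
                  alternative = "greater", control_arm = "control"),
    qpcr = list(generate = TRUE, n_samples = 8L, group_sizes = c(4L, 4L),
                stability_sds = c(0.1, 0.12, 0.15, 0.18, 0.2, 0.25,
                                  rep(0.2, 7)),
                target_log2fc = 0),
    gsea = list(generate = TRUE, n_genes = 2000L, group_sizes = c(3L, 4L),
                planted = list(list(set_id = "PLANTED_DOWN_A", set_size = 40L,
                                    effect = -1.0),
                               list(set_id = "PLANTED_DOWN_B", set_size = 60L,
                                    effect = -1.0)),
                n_decoy_sets = 65L, noise_sd = 1.0,
                n_perm = 500L, metric = "signal_to_noise", or_threshold = 2.0),
    vessels = list(generate = TRUE, n_vessels = 16L, pixel_size = 1.0,
                   base_radius_mean = 5, dilated_radius = 12,
                   prevalence = c(0.4, 0.1), threshold = 0.5,
                   min_object_px = 50L, radius_cutoff_um = 10)
  )
}

#' Validate a study configuration
#'
#' @param config a config list (as from [demo_config()] or parsed from
#'   JSON/YAML via [read_study_config()]).
#' @return Character vector of issues; empty when the config is valid.
#' @export
validate_config <- function(config) {
  issues <- character(0L)
  add <- function(msg) issues <<- c(issues, msg)
  if (is.null(config$seed)) add("missing root seed")
  for (stage in c("cohort", "qpcr", "gsea", "vessels")) {
    blk <- config[[stage]]
    if (is.null(blk)) next
    if (!isTRUE(blk$generate)) {
      for (f in unlist(blk[grepl("(path|csv|gct|cls|gmt)$", names(blk))])) {
        if (!file.exists(f)) add(sprintf("%s: input file not found: %s", stage, f))
      }
      if (!any(grepl("(path|csv|gct|cls|gmt)$", names(blk)))) {
        add(sprintf("%s: neither generator nor input files configured", stage))
      }
    }
  }
  if (!is.null(config$gsea)) {
    if (!is.null(config$gsea$n_perm) && config$gsea$n_perm < 1) {
      add("gsea: n_perm must be >= 1")
    }
    if (!is.null(config$gsea$noise_sd) && config$gsea$noise_sd <= 0) {
      add("gsea: noise_sd must be positive")
    }
  }
  if (!is.null(config$vessels) && !is.null(config$vessels$pixel_size) &&
      config$vessels$pixel_size <= 0) {
    add("vessels: pixel_size must be positive")
  }
  if (!is.null(config$cohort) && !is.null(config$cohort$weight_noise_cv) &&
      config$cohort$weight_noise_cv <= 0) {
    add("cohort: weight_noise_cv must be positive")
  }
  issues
}

#' Read a study configuration from JSON or YAML
#'
#' @param path file ending in `.json`, `.yaml` or `.yml`.
#' @return Config list.
#' @export
read_study_config <- function(path) {
  if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    stop_param("config must be .json or .yaml: %s", path)
  }
}

run_cohort_stage <- function(blk, seed) {
  if (isTRUE(blk$generate)) {
    spec <- default_cohort_spec(weight_noise_cv = blk$weight_noise_cv %||% 0.3,
                                seed = seed)
    cohort <- gen_cohort(spec)$cohort
  } else {
    cohort <- read_cohort_csv(blk$csv)
  }
  alternative <- blk$alternative %||% "greater"
  control <- blk$control_arm %||% cohort$arm[1L]
  inc <- incidence_summary(cohort)
  arms <- inc$arm
  weights <- split(cohort$tumor_weight, factor(cohort$arm, levels = arms))
  kw <- kruskal_wallis(weights)
  poc <- percent_of_control(weights, control = control)
  pair_test <- function(a, b) {
    ia <- inc[inc$arm == a, ]; ib <- inc[inc$arm == b, ]
    ft <- fisher_exact_2x2(matrix(c(ia$count_met, ia$n - ia$count_met,
                                    ib$count_met, ib$n - ib$count_met),
                                  2L, byrow = TRUE), alternative)
    data.frame(arm_a = a, arm_b = b, alternative = alternative,
               p.value = ft$p.value)
  }
  # the two pairwise incidence contrasts of the emulated report:
  # control vs the anti-VEGF arm, and anti-VEGF vs the combination
  tests <- if (all(c("control", "BV", "BV+SC236") %in% arms)) {
    rbind(pair_test("control", "BV"), pair_test("BV", "BV+SC236"),
          pair_test("control", "BV+SC236"))
  } else if (length(arms) >= 2L) {
    pair_test(arms[1L], arms[length(arms)])
  }
  list(cohort = cohort, incidence = inc, kruskal_wallis = kw,
       percent_of_control = poc, fisher_tests = tests,
       params = list(seed = seed, alternative = alternative,
                     control_arm = control))
}

run_qpcr_stage <- function(blk, seed) {
  if (isTRUE(blk$generate)) {
    qp <- gen_qpcr(n_samples = blk$n_samples %||% 8L,
                   stability_sds = blk$stability_sds %||% 0.15,
                   target_log2fc = blk$target_log2fc %||% 0,
                   group_sizes = blk$group_sizes, seed = seed)
    cq <- qp$cq; roles <- qp$roles; group <- qp$group
  } else {
    plate <- read_cq_csv(blk$csv)
    cq <- plate$cq; roles <- plate$roles; group <- blk$group
  }
  res <- genorm_analysis(cq, roles, group = group)
  list(result = res, params = list(seed = seed))
}

run_gsea_stage <- function(blk, seed) {
  if (isTRUE(blk$generate)) {
    planted <- lapply(blk$planted, function(p)
      planted_set_spec(p$set_id, p$set_size, p$effect))
    bundle <- gen_expression(n_genes = blk$n_genes %||% 10000L,
                             group_sizes = blk$group_sizes %||% c(3L, 4L),
                             planted = planted,
                             n_decoy_sets = blk$n_decoy_sets %||% 62L,
                             noise_sd = blk$noise_sd %||% 1.0,
                             seed = seed)
    exprs <- bundle$exprs; classes <- bundle$classes; sets <- bundle$genesets
  } else {
    exprs <- read_gct(blk$gct)
    classes <- read_cls(blk$cls)
    sets <- read_gmt(blk$gmt)
  }
  res <- run_gsea(exprs, classes, sets, metric = blk$metric %||% "signal_to_noise",
                  n_perm = blk$n_perm %||% 5000L, seed = seed)
  list(result = res, filtered = filter_results(res, blk$or_threshold %||% 2.0),
       params = list(seed = seed, n_perm = blk$n_perm %||% 5000L,
                     metric = blk$metric %||% "signal_to_noise",
                     or_threshold = blk$or_threshold %||% 2.0))
}

run_vessel_stage <- function(blk, seed) {
  px <- blk$pixel_size %||% 1.0
  groups <- list()
  if (isTRUE(blk$generate)) {
    n <- blk$n_vessels %||% 16L
    prev <- blk$prevalence %||% c(0.4, 0.1)
    for (g in seq_along(prev)) {
      gseed <- seed + g
      set.seed(gseed)
      dilated <- stats::runif(n) < prev[g]
      radii <- ifelse(dilated, blk$dilated_radius %||% 12,
                      pmax(stats::rnorm(n, blk$base_radius_mean %||% 5, 0.8), 2.5))
      spec <- gen_vessel_field(radii, seed = gseed, pixel_size = px)
      img <- gen_vessel_image(spec)
      groups[[paste0("group", g)]] <- list(image = img$image, truth = img$truth)
    }
  } else {
    for (f in blk$images) {
      groups[[basename(f)]] <- list(image = read_gray_tiff(f), truth = NULL)
    }
  }
  morph <- lapply(groups, function(g)
    analyze_vessel_image(g$image, pixel_size = px,
                         threshold = blk$threshold %||% 0.5,
                         min_object_px = blk$min_object_px %||% 50L))
  cmp <- NULL
  if (length(morph) == 2L) {
    cmp <- radius_distribution_compare(morph[[1L]]$object_radii,
                                       morph[[2L]]$object_radii,
                                       blk$radius_cutoff_um %||% 10)
  }
  list(morphometry = morph, comparison = cmp,
       params = list(seed = seed, pixel_size = px,
                     threshold = blk$threshold %||% 0.5,
                     min_object_px = blk$min_object_px %||% 50L,
                     radius_cutoff_um = blk$radius_cutoff_um %||% 10))
}

#' Run a configured study end to end
#'
#' Executes the configured stages (cohort statistics, geNorm qPCR analysis,
#' gene-set enrichment, vessel morphometry) in order; stages absent from the
#' config are skipped. Each stage draws its seed substream from the root
#' seed. When `out_dir` is given, per-stage TSV reports and a JSON manifest
#' (package version, seeds, parameters) are written; outputs carry no
#' timestamps, so identical config and seed reproduce them byte for byte.
#'
#' @param config config list, see [demo_config()].
#' @param out_dir optional output directory (created if needed).
#' @return Object of class `study_report`: per-stage results plus the
#'   manifest.
#' @export
run_study <- function(config, out_dir = NULL) {
  issues <- validate_config(config)
  if (length(issues)) stop_param("invalid config:\n%s", paste("-", issues, collapse = "\n"))
  seed <- config$seed
  report <- list()
  manifest <- list(package = "xenoquant",
                   version = as.character(utils::packageVersion("xenoquant")),
                   root_seed = seed, stages = list())
  stages <- list(cohort = run_cohort_stage, qpcr = run_qpcr_stage,
                 gsea = run_gsea_stage, vessels = run_vessel_stage)
  for (nm in names(stages)) {
    blk <- config[[nm]]
    if (is.null(blk)) next
    sseed <- substream_seed(seed, nm)
    out <- tryCatch(stages[[nm]](blk, sseed),
                    error = function(e) stop_param("stage '%s' failed: %s", nm,
                                                   conditionMessage(e)))
    report[[nm]] <- out
    manifest$stages[[nm]] <- out$params
  }
  report$manifest <- manifest
  class(report) <- "study_report"
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_study_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$cohort)) {
    write_tsv(report$cohort$incidence, file.path(out_dir, "cohort_incidence.tsv"))
    write_tsv(report$cohort$percent_of_control, file.path(out_dir, "cohort_weights.tsv"))
    kw <- report$cohort$kruskal_wallis
    tests <- rbind(data.frame(arm_a = "(all arms)", arm_b = "",
                              alternative = "kruskal_wallis", p.value = kw$p.value),
                   report$cohort$fisher_tests)
    write_tsv(tests, file.path(out_dir, "cohort_tests.tsv"))
  }
  if (!is.null(report$qpcr)) {
    r <- report$qpcr$result
    write_tsv(data.frame(gene = names(r$M), M = r$M),
              file.path(out_dir, "genorm_M.tsv"))
    write_tsv(data.frame(step = names(r$V), V = r$V),
              file.path(out_dir, "genorm_V.tsv"))
    write_tsv(data.frame(sample = names(r$NF), NF = r$NF),
              file.path(out_dir, "genorm_NF.tsv"))
    write_tsv(data.frame(gene = rownames(r$normalized_targets),
                         r$normalized_targets, check.names = FALSE),
              file.path(out_dir, "genorm_targets.tsv"))
    if (!is.null(r$target_tests)) {
      write_tsv(r$target_tests, file.path(out_dir, "genorm_target_tests.tsv"))
    }
  }
  if (!is.null(report$gsea)) {
    write_gsea_report(report$gsea$result, file.path(out_dir, "gsea_report.tsv"),
                      report$gsea$params$or_threshold)
  }
  if (!is.null(report$vessels)) {
    m <- report$vessels$morphometry
    df <- do.call(rbind, lapply(names(m), function(g) {
      x <- m[[g]]
      data.frame(group = g, mvd = x$mvd, n_objects = length(x$object_radii),
                 mean_inscribed_radius = x$mean_inscribed_radius,
                 fraction_gt_cutoff = x$fraction_gt_cutoff,
                 n_nodes = x$n_nodes, n_endpoints = x$n_endpoints,
                 total_length = x$total_length)
    }))
    write_tsv(df, file.path(out_dir, "vessel_morphometry.tsv"))
    if (!is.null(report$vessels$comparison)) {
      cmp <- report$vessels$comparison
      write_tsv(data.frame(fraction_a = cmp$fraction_a, fraction_b = cmp$fraction_b,
                           p.value = cmp$p.value),
                file.path(out_dir, "vessel_radius_compare.tsv"))
    }
  }
  jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report (seed", x$manifest$root_seed, ")\n")
  if (!is.null(x$cohort)) {
    cat("\n-- Cohort incidence --\n"); print(x$cohort$incidence)
    cat(sprintf("Kruskal-Wallis on weights: H = %.3f, p = %.4g\n",
                x$cohort$kruskal_wallis$H, x$cohort$kruskal_wallis$p.value))
    if (!is.null(x$cohort$fisher_tests)) print(x$cohort$fisher_tests, digits = 3)
  }
  if (!is.null(x$qpcr)) {
    cat("\n-- geNorm --\n")
    cat("ranking:", paste(x$qpcr$result$ranking$ranking, collapse = " > "), "\n")
  }
  if (!is.null(x$gsea)) {
    cat("\n-- GSEA --\n"); print(x$gsea$result)
  }
  if (!is.null(x$vessels)) {
    cat("\n-- Vessels --\n")
    for (g in names(x$vessels$morphometry)) {
      cat(g, ":\n"); print(x$vessels$morphometry[[g]])
    }
    if (!is.null(x$vessels$comparison)) {
      cmp <- x$vessels$comparison
      cat(sprintf("radius > cutoff fractions: %.2f vs %.2f, Fisher p = %.4g\n",
                  cmp$fraction_a, cmp$fraction_b, cmp$p.value))
    }
  }
  invisible(x)
}
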