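# End-to-end orchestration: filter -> species summaries -> rarefaction and
# sample-size standardization -> life-form comparisons -> community
# synchrony -> phylogenetic signal, with one validated config and seeded,
# logged stages.

#' Pipeline configuration
#'
#' Validates and completes the settings for [run_phenology_pipeline()].
#' Unknown keys are rejected before any computation.
#'
#' @param out_dir output directory for the CSV reports.
#' @param min_individuals,min_flowering_days,require_both_years species
#'   filters, see [filter_species()].
#' @param variables phenological variables to rarefy and compare.
#' @param n_std standardized sample sizes.
#' @param B bootstrap replicate counts (rarefaction and synchrony CIs).
#' @param alpha significance level for test selection and year pooling.
#' @param seed master seed; per-stage seeds are derived from it.
#' @param pool_years `"auto"` pools the two years for a variable only when
#'   its year effect is non-significant at `alpha` (mixed-model test);
#'   `"always"`/`"never"` force either mode.
#' @param phi_denominator passed to [synchrony_phi()].
#' @param morisita_bins passed to [morisita_index()].
#' @param tree optional `phylo` object or newick path for the
#'   phylogenetic-signal stage (tip labels = species names).
#' @param n_perm permutations for [signal_test()].
#' @return a validated `pheno_run_config` list.
#' @export
pheno_run_config <- function(out_dir = tempfile("pheno_run_"),
                             min_individuals = 5L, min_flowering_days = 2L,
                             require_both_years = TRUE,
                             variables = c("TFL", "MFL", "VFL", "morisita"),
                             n_std = c(5L, 7L, 12L, 18L, 22L),
                             B = 1000L, alpha = 0.05, seed = 1L,
                             pool_years = c("auto", "always", "never"),
                             phi_denominator = "sd_sum",
                             morisita_bins = "season",
                             tree = NULL, n_perm = 999L) {
  pool_years <- match.arg(pool_years)
  variables <- match.arg(variables, PHENO_VARIABLES, several.ok = TRUE)
  stopifnot(B >= 1L, alpha > 0, alpha < 1, all(n_std >= 1L))
  structure(list(out_dir = out_dir, min_individuals = min_individuals,
                 min_flowering_days = min_flowering_days,
                 require_both_years = require_both_years,
                 variables = variables, n_std = n_std, B = B, alpha = alpha,
                 seed = seed, pool_years = pool_years,
                 phi_denominator = phi_denominator,
                 morisita_bins = morisita_bins, tree = tree, n_perm = n_perm),
            class = "pheno_run_config")
}

# run one stage with uniform error reporting
run_stage <- function(name, log, expr) {
  log(sprintf("stage %s: start", name))
  res <- tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
  log(sprintf("stage %s: done", name))
  res
}

#' Run the full phenology analysis pipeline
#'
#' Executes the whole workflow on a dataset and writes `summaries.csv`,
#' `standardized.csv`, `comparisons.csv`, `synchrony.csv`, `physig.csv`
#' (when a tree is supplied) and `run_log.txt` into `config$out_dir`.
#' Deterministic given the config seed: running twice with the same config
#' produces identical outputs.
#'
#' @param ds a `pheno_dataset`.
#' @param config a [pheno_run_config()].
#' @return (invisibly) a list with elements `filtered`, `summaries`,
#'   `year_effects`, `standardized`, `comparisons`, `synchrony`, `physig`,
#'   `counts`, `files`.
#' @export
run_phenology_pipeline <- function(ds, config = pheno_run_config()) {
  stopifnot(inherits(ds, "pheno_dataset"), inherits(config, "pheno_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  log_lines <- character(0)
  log <- function(msg) log_lines[[length(log_lines) + 1L]] <<- msg
  log(sprintf("phenosynch %s | seed %d | alpha %g | B %d",
              as.character(utils::packageVersion("phenosynch")),
              config$seed, config$alpha, config$B))
  log(sprintf("settings: pool_years=%s phi_denominator=%s morisita_bins=%s n_std=%s",
              config$pool_years, config$phi_denominator, config$morisita_bins,
              paste(config$n_std, collapse = ",")))

  n_species_in <- length(unique(ds$records$species))
  filtered <- run_stage("filter", log, filter_species(
    ds, min_flowering_days = config$min_flowering_days,
    min_individuals = config$min_individuals,
    require_both_years = config$require_both_years))
  dropped <- attr(filtered, "dropped")
  log(sprintf("filter: %d species in = %d kept + %d dropped", n_species_in,
              length(unique(filtered$records$species)), nrow(dropped)))

  summaries <- run_stage("summaries", log, summarize_species(
    filtered, morisita_bins = config$morisita_bins))
  write_summary_table(summaries, file.path(config$out_dir, "summaries.csv"))

  # year-effect screen per variable (gamma GLMM; gaussian for skewness),
  # used only to decide pooling when pool_years = "auto"
  year_effects <- run_stage("year_effects", log, {
    years <- as.integer(names(filtered$calendars))
    if (length(years) < 2L || config$pool_years != "auto") NULL else {
      out <- lapply(config$variables, function(v) {
        d <- summaries[is.finite(summaries[[v]]), ]
        d$year_f <- d$year - min(d$year)
        fam <- if (v == "skewness" || any(d[[v]] <= 0)) "gaussian" else "gamma"
        p <- tryCatch({
          fit <- suppressWarnings(fit_pheno_glmm(d, v, c("year_f", "n"), family = fam))
          fit$coefficients["year_f", "p_wald"]
        }, error = function(e) NA_real_)
        data.frame(variable = v, family = fam, p_year = p,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, out)
    }
  })

  standardized <- run_stage("rarefaction", log, standardize_estimates(
    filtered, variables = config$variables, n_std = config$n_std,
    B = config$B, seed = derive_seed(config$seed, "rarefaction"),
    pool_years = TRUE, morisita_bins = config$morisita_bins))
  utils::write.csv(standardized, file.path(config$out_dir, "standardized.csv"),
                   row.names = FALSE)
  log(sprintf("rarefaction: forms selected: %s",
              paste(names(attr(standardized, "forms")),
                    attr(standardized, "forms"), sep = "=", collapse = ", ")))

  comparisons <- run_stage("comparisons", log, {
    rows <- list()
    for (v in unique(standardized$variable)) {
      for (ns in config$n_std) {
        d <- standardized[standardized$variable == v & standardized$n_std == ns, ]
        cmp <- compare_groups(d$value, d$life_form, alpha = config$alpha)
        cmp$variable <- v
        cmp$n_std <- ns
        rows[[length(rows) + 1L]] <- cmp
      }
    }
    do.call(rbind, rows)
  })
  utils::write.csv(comparisons, file.path(config$out_dir, "comparisons.csv"),
                   row.names = FALSE)

  synchrony <- run_stage("synchrony", log, {
    rows <- list()
    for (yr in as.integer(names(filtered$calendars))) {
      for (lf in intersect(LIFE_FORMS, unique(filtered$records$life_form))) {
        M <- build_community_matrix(filtered, yr, lf)
        if (ncol(M) < 2L) next
        ci <- bootstrap_group_ci(M, "phi", B = config$B,
                                 seed = derive_seed(config$seed, c("phi", yr, lf)))
        on <- species_onsets(filtered, yr, lf)
        sk_ci <- bootstrap_group_ci(on, "skewness", B = config$B,
                                    seed = derive_seed(config$seed, c("skew", yr, lf)))
        sk_test <- if (length(on) >= 8L) onset_skewness_test(on) else
          list(skewness = moment_skewness(as.numeric(on)), statistic = NA_real_,
               p.value = NA_real_)
        rows[[length(rows) + 1L]] <- data.frame(
          year = yr, life_form = lf, n_species = ncol(M),
          phi = ci$estimate, phi_low = ci$ci_low, phi_high = ci$ci_high,
          onset_skewness = sk_test$skewness, k2 = sk_test$statistic,
          p_skew = sk_test$p.value,
          skew_low = sk_ci$ci_low, skew_high = sk_ci$ci_high,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  utils::write.csv(synchrony, file.path(config$out_dir, "synchrony.csv"),
                   row.names = FALSE)

  physig <- NULL
  if (!is.null(config$tree)) {
    physig <- run_stage("physig", log, {
      tree <- if (inherits(config$tree, "phylo")) prepare_phylogeny(config$tree)
              else read_phylogeny(config$tree)
      rows <- lapply(config$variables, function(v) {
        x <- tapply(summaries[[v]], summaries$species, mean, na.rm = TRUE)
        x <- x[is.finite(x)]
        common <- intersect(tree$tip.label, names(x))
        if (length(common) < 4L) return(NULL)
        tr <- ape::keep.tip(tree, common)
        st <- signal_test(tr, x[common], n_perm = config$n_perm,
                          seed = derive_seed(config$seed, c("physig", v)))
        data.frame(variable = v, n_tips = length(common), K = st$K,
                   p_permutation = st$p_permutation, stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })
    if (!is.null(physig)) {
      utils::write.csv(physig, file.path(config$out_dir, "physig.csv"),
                       row.names = FALSE)
    }
  }

  counts <- list(species_in = n_species_in,
                 species_kept = length(unique(filtered$records$species)),
                 species_dropped = nrow(dropped))
  log(sprintf("reconciliation: %d = %d + %d", counts$species_in,
              counts$species_kept, counts$species_dropped))
  writeLines(log_lines, log_path)

  invisible(list(filtered = filtered, summaries = summaries,
                 year_effects = year_effects, standardized = standardized,
                 comparisons = comparisons, synchrony = synchrony,
                 physig = physig, counts = counts,
                 files = list.files(config$out_dir, full.names = TRUE)))
}
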