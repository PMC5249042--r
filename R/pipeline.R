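#' Default end-to-end run configuration
#'
#' Assembles the four scenario objects plus run-level options (seed,
#' aggregation method, test sidedness, maximum-lifespan quantile) into
#' one configuration list consumed by [run_pipeline()].
#'
#' @param seed Integer seed used for every stochastic stage.
#' @param stress,lifespan,expression,activity Scenario objects; defaults
#'   are the package defaults. To keep the default pipeline quick,
#'   `expression` defaults to 2000 genes.
#' @param method Node-aggregation method (`"weighted"` or `"sum"`).
#' @param sided Sidedness of the correlation-difference test.
#' @param quantile Maximum-lifespan quantile.
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L,
                               stress = stress_scenario(),
                               lifespan = lifespan_scenario(),
                               expression = expression_scenario(n_genes = 2000),
                               activity = activity_scenario(),
                               method = c("weighted", "sum"),
                               sided = c("one", "two"),
                               quantile = 0.9) {
  structure(list(seed = as.integer(seed), stress = stress,
                 lifespan = lifespan, expression = expression,
                 activity = activity, method = match.arg(method),
                 sided = match.arg(sided), quantile = quantile),
            class = "run_config")
}

#' Read a run configuration from a plain-text file
#'
#' The format is INI-like: `[section]` headers (`run`, `stress`,
#' `lifespan`, `expression`, `activity`) with one `key = value` pair per
#' line; `#` starts a comment. Keys are the scenario constructor
#' arguments; unlisted keys keep their defaults. The `run` section takes
#' `seed`, `method`, `sided`, `quantile`.
#'
#' @param path Path to the config file.
#' @return A `run_config` list, as from [default_run_config()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- "run"
  vals <- list(run = list(), stress = list(), lifespan = list(),
               expression = list(), activity = list())
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      if (!section %in% names(vals)) {
        stop_param("unknown config section [%s]", section)
      }
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      key <- trimws(kv[1L])
      raw <- trimws(paste(kv[-1L], collapse = "="))
      num <- suppressWarnings(as.numeric(raw))
      vals[[section]][[key]] <- if (is.na(num)) raw else num
    } else {
      stop_param("unparseable config line: '%s'", ln)
    }
  }
  run <- vals$run
  default_run_config(
    seed = if (is.null(run$seed)) 1L else run$seed,
    stress = do.call(stress_scenario, vals$stress),
    lifespan = do.call(lifespan_scenario, vals$lifespan),
    expression = do.call(expression_scenario, vals$expression),
    activity = do.call(activity_scenario, vals$activity),
    method = if (is.null(run$method)) "weighted" else run$method,
    sided = if (is.null(run$sided)) "one" else run$sided,
    quantile = if (is.null(run$quantile)) 0.9 else run$quantile)
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic analysis pipeline
#'
#' Executes every stage on synthetic data: generates lifespan cohorts and
#' compares the genotypes; generates stress cohorts for both genotypes,
#' summarizes each age cohort, correlates mean survival with age, and
#' tests the difference between the genotypes' correlations; generates a
#' gene table and toy pathway and scores the nodes; generates a DAM file,
#' reads it back and profiles daily activity. All outputs are TSV (plus
#' one DOT graph), a plain-text report, and a JSON manifest recording the
#' seed, a config hash and the package version, so a rerun with the same
#' configuration reproduces byte-identical files.
#'
#' @param config A `run_config`, path to a config file, or `NULL` for
#'   [default_run_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the key computed objects and the paths
#'   written.
#' @export
run_pipeline <- function(config = NULL, out_dir) {
  if (is.null(config)) config <- default_run_config()
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  paths <- character(0)
  report <- character(0)
  log_stage <- function(fmt, ...) {
    report <<- c(report, sprintf(fmt, ...))
    message(sprintf(fmt, ...))
  }

  # -- lifespan -----------------------------------------------------------
  lc <- gen_lifespan_cohorts(config$lifespan, seed = config$seed)
  cmp <- compare_lifespan(lc$control, lc$overexpression,
                          quantile = config$quantile)
  life_tab <- data.frame(
    group = c("control", "overexpression"),
    median = c(cmp$m_ctrl, cmp$m_exp),
    d_m_pct = c(NA, cmp$d_m),
    t90 = c(cmp$t90_ctrl, cmp$t90_exp),
    d_90_pct = c(NA, cmp$d_90),
    p_mantel_cox = c(NA, cmp$p_median),
    p_gehan_wilcoxon = c(NA, cmp$p_median_gehan),
    p_wang_allison = c(NA, cmp$p_max),
    n = c(cmp$n_ctrl, cmp$n_exp))
  paths <- c(paths, write_tsv(life_tab, p("lifespan_comparison.tsv")))
  log_stage("lifespan: %d + %d flies, dM = %+.1f%%",
            cmp$n_ctrl, cmp$n_exp, cmp$d_m)

  # -- stress-resistance dynamics ----------------------------------------
  summaries <- list()
  trend <- list()
  for (g in c("control", "overexpression")) {
    cohorts <- gen_stress_cohorts(config$stress, seed = config$seed,
                                  genotype = g)
    sm <- do.call(rbind, lapply(cohorts, function(co) {
      s <- summarize_cohort(co)
      data.frame(stress = co$stress, sex = co$sex, genotype = co$genotype,
                 age_days = co$age_days, mean = s$mean, sem = s$sem,
                 median = s$median, t90 = s$t90, n = s$n)
    }))
    summaries[[g]] <- sm
    ct <- age_survival_correlation(sm$age_days, sm$mean)
    trend[[g]] <- data.frame(stress = sm$stress[1L], sex = sm$sex[1L],
                             genotype = g, r = ct$r, n = ct$n, p = ct$p)
  }
  sum_tab <- do.call(rbind, summaries)
  rownames(sum_tab) <- NULL
  trend_tab <- do.call(rbind, trend)
  rownames(trend_tab) <- NULL
  cc <- compare_correlations(trend_tab$r[1L], trend_tab$n[1L],
                             trend_tab$r[2L], trend_tab$n[2L],
                             sided = config$sided)
  cc_tab <- data.frame(stress = trend_tab$stress[1L],
                       sex = trend_tab$sex[1L],
                       r_control = trend_tab$r[1L],
                       r_overexpression = trend_tab$r[2L],
                       z_stat = cc$z_stat, p = cc$p, sided = cc$sided)
  paths <- c(paths,
             write_tsv(sum_tab, p("stress_cohort_summaries.tsv")),
             write_tsv(trend_tab, p("age_survival_correlation.tsv")),
             write_tsv(cc_tab, p("correlation_comparison.tsv")))
  log_stage("stress: %d cohorts, age-survival r = %.3f (control) / %.3f (overexpression)",
            nrow(sum_tab), trend_tab$r[1L], trend_tab$r[2L])

  # -- pathway scoring ----------------------------------------------------
  stats <- gen_gene_stats(config$expression, seed = config$seed)
  graph <- gen_toy_pathway(n_nodes = 8,
                           genes_per_node = c(1, 2, 3, 4, 2, 1, 0, 5),
                           seed = config$seed)
  # toy membership must point at generated genes: remap onto stats ids
  graph <- remap_members(graph, stats$gene_id, seed = config$seed)
  scores <- suppressMessages(score_pathway(graph, stats,
                                           method = config$method))
  paths <- c(paths, export_scores(scores, p("node_scores.tsv"), "tsv"))
  paths <- c(paths, export_scores(scores, p("node_scores.dot"), "dot",
                                  graph = graph))
  log_stage("pathways: %d nodes scored (%s), %d unscored",
            sum(scores$scored), config$method, sum(!scores$scored))

  # -- activity -----------------------------------------------------------
  dam_path <- p("synthetic_dam.txt")
  gen_dam_file(config$activity, seed = config$seed, path = dam_path)
  series <- read_dam(dam_path)[seq_len(config$activity$n_channels)]
  prof <- daily_profile(series, bin_minutes = 10)
  prof_tab <- data.frame(zt_bin = names(prof$profile),
                         mean_counts = as.numeric(prof$profile))
  paths <- c(paths, dam_path,
             write_tsv(prof_tab, p("activity_profile.tsv")),
             write_tsv(prof$daily_totals, p("activity_daily_totals.tsv")))
  log_stage("activity: %d channels, %d complete fly-days",
            config$activity$n_channels, nrow(prof$daily_totals))

  # -- manifest and report ------------------------------------------------
  cfg_file <- p("config_used.txt")
  writeLines(deparse_config(config), cfg_file)
  manifest <- list(seed = config$seed,
                   config_md5 = unname(tools::md5sum(cfg_file)),
                   package_version = as.character(utils::packageVersion("flyspan")),
                   files = basename(c(paths, cfg_file)))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  writeLines(report, p("report.txt"))
  invisible(list(config = config, lifespan = cmp, summaries = sum_tab,
                 trend = trend_tab, correlation_comparison = cc,
                 scores = scores, profile = prof,
                 paths = c(paths, cfg_file, p("manifest.json"),
                           p("report.txt"))))
}

# Reassign node memberships to ids drawn from the generated gene table so
# the toy pathway and gene table refer to the same universe.
remap_members <- function(graph, gene_ids, seed = 1L) {
  sizes <- lengths(graph$members)
  total <- sum(sizes)
  if (total > length(gene_ids)) {
    stop_param("gene table too small to populate the toy pathway")
  }
  picked <- with_seed(seed + 1L, sample(gene_ids, total))
  at <- 0L
  members <- graph$members
  for (i in seq_along(members)) {
    k <- sizes[i]
    members[[i]] <- if (k > 0) picked[at + seq_len(k)] else character(0)
    at <- at + k
  }
  pathway_graph(graph$pathway_id, graph$nodes, members, graph$edges)
}

deparse_config <- function(config) {
  sec <- function(name, x, keys) {
    c(sprintf("[%s]", name),
      vapply(keys, function(k) sprintf("%s = %s", k, format(x[[k]])),
             character(1)))
  }
  c(sec("run", config, c("seed", "method", "sided", "quantile")),
    sec("stress", config$stress,
        c("stress_name", "baseline_mean_survival", "decline_rate",
          "genotype_effect", "sex_effect", "census_interval",
          "max_duration", "distribution", "weibull_shape")),
    sec("lifespan", config$lifespan,
        c("gompertz_a", "gompertz_b", "genotype_effect", "n_per_group",
          "census_interval")),
    sec("expression", config$expression,
        c("n_genes", "logfc_effect_sd", "cpm_log_mean", "cpm_log_sd",
          "fraction_null")),
    sec("activity", config$activity,
        c("n_channels", "days_ld", "days_dd", "mesor", "amplitude",
          "peak_zt", "period", "noise_dispersion",
          "acquisition_interval")))
}
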