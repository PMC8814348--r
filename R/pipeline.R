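#' Configuration for an end-to-end evaluation pipeline run
#'
#' Collects every tunable of the pipeline into a validated list. Stages are
#' run in the fixed order simulate, efa, dematel, danp, topsis; any subset
#' may be enabled, as long as each enabled stage can find its inputs either
#' from an earlier stage or from the `inputs` files. This makes partial
#' pipelines first-class: for instance, the bundled case study supplies
#' published weights and normalized scores, so only the TOPSIS stage runs.
#'
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "efa", "dematel", "danp", "topsis")`.
#' @param seed Integer seed driving every stochastic stage.
#' @param outdir Optional directory; when set, each stage writes its
#'   artifacts (CSV/JSON) there.
#' @param mode `"per-dimension"` (independent DEMATEL/DANP/TOPSIS within
#'   each dimension; the default, matching a framework whose dimensions are
#'   constructed to be independent) or `"pooled"` (one cross-dimension
#'   analysis over all criteria).
#' @param eigen_threshold Kaiser retention threshold for the EFA stage.
#' @param loading_cutoff Minimum absolute rotated loading to keep an item.
#' @param consensus_threshold_pct Expert-consensus gap-ratio threshold (%);
#'   the pipeline halts in the DEMATEL stage when the gap ratio is not
#'   below it.
#' @param directions Optional named vector of `"benefit"`/`"cost"` per
#'   criterion; default all benefit.
#' @param dimension_labels Optional dimension names for the EFA stage.
#' @param simulate Optional list with elements `factor_spec`
#'   ([factor_spec()]), `n_respondents`, `influence_specs` (named list of
#'   [influence_spec()], one per dimension, or a single spec for pooled
#'   mode), and `performance_spec` ([performance_spec()]); defaults via
#'   [default_simulation_specs()].
#' @param inputs Optional list of file-based inputs for stages whose
#'   upstream is disabled: `panel_csv`, `survey_csvs` (named list,
#'   dimension -> vector of per-expert CSV paths), `scores_csvs` (vector of
#'   per-expert CSV paths), `decision_csv` plus `decision_normalized`,
#'   `weights_csv` (criterion, dimension, weight columns), `framework`
#'   (named list dimension -> criterion ids).
#' @return A validated object of class `pipeline_config`.
#' @export
pipeline_config <- function(stages = c("simulate", "efa", "dematel", "danp", "topsis"),
                            seed = 1L,
                            outdir = NULL,
                            mode = c("per-dimension", "pooled"),
                            eigen_threshold = 1,
                            loading_cutoff = 0.6,
                            consensus_threshold_pct = 5,
                            directions = NULL,
                            dimension_labels = NULL,
                            simulate = NULL,
                            inputs = list()) {
  mode <- match.arg(mode)
  all_stages <- c("simulate", "efa", "dematel", "danp", "topsis")
  if (!all(stages %in% all_stages)) {
    nim_stop("nimcdm_config_error",
             sprintf("unknown stage(s): %s",
                     paste(setdiff(stages, all_stages), collapse = ", ")))
  }
  if (eigen_threshold <= 0 || loading_cutoff <= 0) {
    nim_stop("nimcdm_config_error", "thresholds must be positive")
  }
  if (consensus_threshold_pct < 0) {
    nim_stop("nimcdm_config_error", "`consensus_threshold_pct` must be non-negative")
  }
  structure(
    list(stages = all_stages[all_stages %in% stages],
         seed = as.integer(seed),
         outdir = outdir,
         mode = mode,
         eigen_threshold = eigen_threshold,
         loading_cutoff = loading_cutoff,
         consensus_threshold_pct = consensus_threshold_pct,
         directions = directions,
         dimension_labels = dimension_labels,
         simulate = simulate,
         inputs = inputs),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [pipeline_config()] (specs under `simulate` are given as plain lists:
#'   e.g. `factor_spec: {loading_pattern: [[...]], noise_sd: 0.5}`).
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    nim_stop("nimcdm_config_error", sprintf("config file not found: %s", path))
  }
  y <- yaml::read_yaml(path)
  sim <- y$simulate
  if (!is.null(sim)) {
    if (!is.null(sim$factor_spec)) {
      fs <- sim$factor_spec
      sim$factor_spec <- factor_spec(
        do.call(rbind, lapply(fs$loading_pattern, as.numeric)),
        noise_sd = fs$noise_sd %||% 0.5,
        missing_rate = fs$missing_rate %||% 0)
    }
    if (!is.null(sim$influence_specs)) {
      sim$influence_specs <- lapply(sim$influence_specs, function(s) {
        influence_spec(do.call(rbind, lapply(s$ground_truth, as.numeric)),
                       expert_count = s$expert_count,
                       disagreement = s$disagreement %||% 0)
      })
    }
    if (!is.null(sim$performance_spec)) {
      ps <- sim$performance_spec
      sim$performance_spec <- performance_spec(
        do.call(rbind, lapply(ps$true_quality, as.numeric)),
        expert_count = ps$expert_count,
        score_sd = ps$score_sd %||% 1)
    }
  }
  pipeline_config(
    stages = y$stages %||% c("simulate", "efa", "dematel", "danp", "topsis"),
    seed = y$seed %||% 1L,
    outdir = y$outdir,
    mode = y$mode %||% "per-dimension",
    eigen_threshold = y$eigen_threshold %||% 1,
    loading_cutoff = y$loading_cutoff %||% 0.6,
    consensus_threshold_pct = y$consensus_threshold_pct %||% 5,
    directions = if (!is.null(y$directions)) unlist(y$directions),
    dimension_labels = y$dimension_labels,
    simulate = sim,
    inputs = y$inputs %||% list()
  )
}

#' Default synthetic study conditions for the simulate stage
#'
#' Emulates the survey scales of the original elicitation: a 103-respondent
#' Likert panel over 8 items with two planted factors (salient loadings
#' 0.8, unique noise sd 0.5, 2% missing responses); per dimension, a panel
#' of 34 experts scoring 4x4 direct influence around a fixed ground truth
#' with 2% cell disagreement; and 15 experts scoring three alternative
#' buildings on the 0-10 scale with scoring noise sd 1.
#'
#' @return A list suitable as the `simulate` element of
#'   [pipeline_config()].
#' @export
default_simulation_specs <- function() {
  items <- c(paste0("C1", 1:4), paste0("C2", 1:4))
  L <- matrix(0, 8, 2, dimnames = list(items, c("F1", "F2")))
  L[1:4, 1] <- 0.8
  L[5:8, 2] <- 0.8
  gt1 <- matrix(c(0, 1, 1, 2,
                  2, 0, 2, 3,
                  3, 3, 0, 3,
                  1, 2, 1, 0),
                4, 4, byrow = TRUE,
                dimnames = list(items[1:4], items[1:4]))
  gt2 <- matrix(c(0, 2, 2, 1,
                  1, 0, 2, 1,
                  1, 1, 0, 1,
                  3, 2, 3, 0),
                4, 4, byrow = TRUE,
                dimnames = list(items[5:8], items[5:8]))
  quality <- matrix(c(4, 3, 4, 3, 6, 4, 5, 7,
                      6, 5, 3, 5, 4, 7, 4, 5,
                      4, 6, 7, 6, 6, 5, 7, 4),
                    nrow = 3, byrow = TRUE,
                    dimnames = list(c("SYUH", "GZMH", "ZCWH"), items))
  list(
    factor_spec = factor_spec(L, noise_sd = 0.5, missing_rate = 0.02),
    n_respondents = 103L,
    influence_specs = list(D1 = influence_spec(gt1, 34L, disagreement = 0.02),
                           D2 = influence_spec(gt2, 34L, disagreement = 0.02)),
    performance_spec = performance_spec(quality, 15L, score_sd = 1)
  )
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    e$message <- sprintf("[stage %s] %s", stage, conditionMessage(e))
    class(e) <- unique(c("nimcdm_stage_error", class(e)))
    stop(e)
  })
}

#' Run the evaluation pipeline end-to-end
#'
#' Executes the enabled stages in order — simulate (synthetic surveys),
#' efa (framework construction), dematel (total influence and INRM, per
#' dimension by default), danp (limit-supermatrix influence weights),
#' topsis (per-dimension ranking of alternatives) — threading each stage's
#' output into the next, and returns a structured run report. A failure in
#' any stage aborts with the stage name prefixed to the error. Identical
#' config and seed give identical outputs.
#'
#' @param config A [pipeline_config()] (or a YAML path, loaded via
#'   [load_pipeline_config()]).
#' @return An object of class `run_report`; see [render_report()].
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  st <- config$stages
  inputs <- config$inputs
  outdir <- config$outdir
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  save_mat <- function(m, file) {
    if (!is.null(outdir)) write_matrix_csv(m, file.path(outdir, file))
  }
  report <- list(stages = list())
  panel <- NULL; surveys <- NULL; scores <- NULL
  framework <- NULL; weights <- NULL; decision <- NULL
  decision_normalized <- isTRUE(inputs$decision_normalized)

  if ("simulate" %in% st) {
    run_stage("simulate", {
      sim <- config$simulate %||% default_simulation_specs()
      if (!is.null(sim$factor_spec)) {
        panel <- gen_likert_panel(sim$factor_spec, sim$n_respondents %||% 103L,
                                  seed = config$seed)
        save_mat(unclass(panel), "likert_panel.csv")
      }
      if (!is.null(sim$influence_specs)) {
        surveys <- lapply(seq_along(sim$influence_specs), function(i) {
          gen_influence_survey(sim$influence_specs[[i]], seed = config$seed + i)
        })
        names(surveys) <- names(sim$influence_specs)
      }
      if (!is.null(sim$performance_spec)) {
        scores <- gen_performance_scores(sim$performance_spec,
                                         seed = config$seed + 100L)
      }
      report$stages$simulate <- list(
        n_respondents = if (!is.null(panel)) nrow(panel),
        n_items = if (!is.null(panel)) ncol(panel),
        influence_dimensions = names(surveys),
        expert_counts = vapply(surveys %||% list(), length, integer(1)),
        n_score_experts = length(scores %||% list()))
    })
  }

  if ("efa" %in% st) {
    run_stage("efa", {
      if (is.null(panel)) {
        if (is.null(inputs$panel_csv)) {
          nim_stop("nimcdm_config_error", "efa enabled but no panel available")
        }
        panel <- load_matrix_csv(inputs$panel_csv)
      }
      R <- compute_correlation(panel)
      L <- extract_and_rotate(R, config$eigen_threshold)
      framework <- assign_items(L, config$loading_cutoff, config$dimension_labels)
      rel <- reliability_stats(panel, framework, L)
      save_mat(L$loadings, "loadings.csv")
      report$stages$efa <- list(
        n_used = R$n_used,
        eigenvalues = L$eigenvalues,
        retained_factors = length(L$retained),
        dimensions = framework$dimensions,
        deleted_items = framework$deleted,
        cronbach_alpha = rel$cronbach_alpha,
        kmo = rel$kmo,
        cumulative_variance_pct = rel$cumulative_variance_pct)
    })
  }
  if (is.null(framework) && !is.null(inputs$framework)) {
    framework <- dimension_partition(inputs$framework)$blocks
  }

  dematel_out <- NULL
  if ("dematel" %in% st) {
    run_stage("dematel", {
      if (is.null(surveys)) {
        if (is.null(inputs$survey_csvs)) {
          nim_stop("nimcdm_config_error", "dematel enabled but no surveys available")
        }
        surveys <- lapply(inputs$survey_csvs, function(paths) {
          structure(lapply(paths, load_matrix_csv), class = "influence_survey")
        })
      }
      dematel_out <- lapply(names(surveys), function(d) {
        agg <- aggregate_experts(surveys[[d]], config$consensus_threshold_pct)
        if (!agg$consensus$stable) {
          nim_stop("nimcdm_consensus_error",
                   sprintf("expert consensus not reached for %s (gap ratio %.2f%% >= %.2f%%)",
                           d, agg$consensus$gap_ratio_pct,
                           agg$consensus$threshold_pct))
        }
        Tm <- total_influence(normalize_direct(agg$average))
        inrm <- inrm_profile(Tm)
        save_mat(Tm$values, sprintf("total_influence_%s.csv", d))
        if (!is.null(outdir)) {
          utils::write.csv(inrm$nodes,
                           file.path(outdir, sprintf("inrm_nodes_%s.csv", d)),
                           row.names = FALSE)
          utils::write.csv(inrm$edges,
                           file.path(outdir, sprintf("inrm_edges_%s.csv", d)),
                           row.names = FALSE)
        }
        list(consensus = agg$consensus, total = Tm, inrm = inrm)
      })
      names(dematel_out) <- names(surveys)
      report$stages$dematel <- lapply(dematel_out, function(x) list(
        gap_ratio_pct = x$consensus$gap_ratio_pct,
        stable = x$consensus$stable,
        total_influence = x$total$values,
        inrm_nodes = x$inrm$nodes,
        inrm_edges = x$inrm$edges))
    })
  }

  if ("danp" %in% st) {
    run_stage("danp", {
      if (is.null(dematel_out)) {
        nim_stop("nimcdm_config_error", "danp enabled but the dematel stage did not run")
      }
      if (config$mode == "pooled") {
        if (length(dematel_out) != 1L) {
          nim_stop("nimcdm_config_error",
                   "pooled mode expects a single cross-dimension influence survey")
        }
        Tm <- dematel_out[[1L]]$total
        part <- if (!is.null(framework)) {
          if (inherits(framework, "evaluation_framework")) framework$dimensions
          else framework
        } else {
          list(D1 = rownames(Tm$values))
        }
        Tca <- block_normalize(Tm, part)
        Wa <- unweighted_supermatrix(Tca)
        Ww <- weighted_supermatrix(dimension_influence(Tm, part), Wa)
        ws <- limit_weights(Ww)
        weights <- ws
        report$stages$danp <- list(weights = ws$weights,
                                    convergence = list(pooled = ws$convergence))
      } else {
        per_dim <- lapply(names(dematel_out), function(d) {
          Tm <- dematel_out[[d]]$total
          Tca <- block_normalize(Tm, stats::setNames(list(rownames(Tm$values)), d))
          Ww <- weighted_supermatrix(NULL, unweighted_supermatrix(Tca))
          limit_weights(Ww)
        })
        names(per_dim) <- names(dematel_out)
        tab <- do.call(rbind, lapply(names(per_dim), function(d) {
          w <- per_dim[[d]]$weights
          data.frame(criterion = w$criterion, dimension = d,
                     weight = w$criterion_local, stringsAsFactors = FALSE)
        }))
        weights <- stats::setNames(tab$weight, tab$criterion)
        report$stages$danp <- list(
          weights = tab,
          convergence = lapply(per_dim, `[[`, "convergence"))
      }
      if (!is.null(outdir)) {
        wtab <- report$stages$danp$weights
        utils::write.csv(wtab, file.path(outdir, "influence_weights.csv"),
                         row.names = FALSE)
      }
    })
  }

  if ("topsis" %in% st) {
    run_stage("topsis", {
      if (is.null(weights)) {
        if (is.null(inputs$weights_csv)) {
          nim_stop("nimcdm_config_error", "topsis enabled but no weights available")
        }
        wdf <- utils::read.csv(inputs$weights_csv, stringsAsFactors = FALSE,
                               fileEncoding = "UTF-8")
        if (!all(c("criterion", "dimension", "weight") %in% colnames(wdf))) {
          nim_stop("nimcdm_schema_error",
                   "weights CSV needs criterion, dimension, weight columns")
        }
        weights <- stats::setNames(wdf$weight, wdf$criterion)
        if (is.null(framework)) {
          framework <- split(wdf$criterion, wdf$dimension)
        }
      }
      if (is.null(scores)) {
        if (!is.null(inputs$scores_csvs)) {
          scores <- lapply(inputs$scores_csvs, load_matrix_csv)
        } else if (!is.null(inputs$decision_csv)) {
          decision <- load_matrix_csv(inputs$decision_csv)
        } else {
          nim_stop("nimcdm_config_error", "topsis enabled but no scores available")
        }
      }
      fw <- if (!is.null(framework)) framework else {
        cols <- if (!is.null(decision)) colnames(decision) else colnames(scores[[1L]])
        list(D1 = cols)
      }
      dims <- if (inherits(fw, "evaluation_framework")) fw$dimensions else fw
      res <- if (!is.null(decision) && decision_normalized) {
        # published normalized values: run TOPSIS directly per dimension
        out <- lapply(names(dims), function(d) {
          cols <- dims[[d]]
          w <- extract_weights(weights, cols)[cols]
          dirs <- if (!is.null(config$directions)) {
            dd <- config$directions[cols]; dd[is.na(dd)] <- "benefit"; unname(dd)
          }
          topsis(decision[, cols, drop = FALSE], w / sum(w), dirs,
                 normalized = TRUE)
        })
        stats::setNames(out, names(dims))
      } else {
        evaluate_by_dimension(if (!is.null(decision)) decision else scores,
                              dims, weights, config$directions,
                              mode = if (config$mode == "pooled") "pooled"
                                     else "per-dimension")
      }
      proximity <- lapply(res, function(r) r$proximity)
      ranking <- lapply(res, function(r) r$ranking)
      report$stages$topsis <- list(results = res,
                                    proximity = proximity,
                                    ranking = ranking)
      if (!is.null(outdir)) {
        summary_tab <- do.call(rbind, lapply(names(res), function(d) {
          data.frame(dimension = d,
                     alternative = names(res[[d]]$proximity),
                     proximity = unname(res[[d]]$proximity),
                     rank = match(names(res[[d]]$proximity), res[[d]]$ranking),
                     stringsAsFactors = FALSE)
        }))
        utils::write.csv(summary_tab,
                         file.path(outdir, "topsis_summary.csv"),
                         row.names = FALSE)
      }
    })
  }

  cfg_public <- config[setdiff(names(config), "outdir")]
  report$provenance <- list(
    seed = config$seed,
    mode = config$mode,
    config_hash = fnv1a_hash(utils::capture.output(utils::str(cfg_public))),
    package_version = as.character(utils::packageVersion("nimcdm")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  report <- structure(report, class = "run_report")
  if (!is.null(outdir)) {
    writeLines(render_report(report, "json"), file.path(outdir, "report.json"))
    writeLines(render_report(report, "markdown"), file.path(outdir, "report.md"))
  }
  report
}

#' Render a pipeline run report
#'
#' JSON carries full precision for machine consumption; the markdown
#' rendering rounds to 3 decimals for human reading and includes the
#' per-dimension proximity table and INRM node/edge listings.
#'
#' @param report A [run_pipeline()] result.
#' @param format `"json"` or `"markdown"`.
#' @param include_timestamp Drop the timestamp line when `FALSE`, making
#'   repeat renderings of identical runs byte-identical.
#' @return A character vector of lines (markdown) or a JSON string.
#' @export
render_report <- function(report, format = c("json", "markdown"),
                          include_timestamp = TRUE) {
  stopifnot(inherits(report, "run_report"))
  format <- match.arg(format)
  prov <- report$provenance
  if (!include_timestamp) prov$timestamp <- NULL
  if (format == "json") {
    body <- list(provenance = prov, stages = strip_heavy(report$stages))
    return(as.character(jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA,
                                         dataframe = "rows", pretty = TRUE)))
  }
  lines <- c("# Evaluation pipeline report", "",
             sprintf("- seed: %d", prov$seed),
             sprintf("- mode: %s", prov$mode),
             sprintf("- config hash: %s", prov$config_hash),
             sprintf("- package version: %s", prov$package_version))
  if (!is.null(prov$timestamp)) {
    lines <- c(lines, sprintf("- timestamp: %s", prov$timestamp))
  }
  s <- report$stages
  if (!is.null(s$efa)) {
    lines <- c(lines, "", "## Framework (EFA)",
               sprintf("- complete cases used: %d", s$efa$n_used),
               sprintf("- retained factors: %d", s$efa$retained_factors),
               sprintf("- cumulative variance: %.3f%%", s$efa$cumulative_variance_pct),
               sprintf("- KMO: %.3f", s$efa$kmo),
               sprintf("- Cronbach alpha (overall): %.3f", s$efa$cronbach_alpha[["overall"]]),
               vapply(names(s$efa$dimensions), function(d) {
                 sprintf("- %s: %s", d, paste(s$efa$dimensions[[d]], collapse = ", "))
               }, character(1)))
  }
  if (!is.null(s$dematel)) {
    lines <- c(lines, "", "## Influence structure (DEMATEL)")
    for (d in names(s$dematel)) {
      x <- s$dematel[[d]]
      lines <- c(lines,
                 sprintf("### %s (consensus gap ratio %.3f%%)", d, x$gap_ratio_pct),
                 md_table(x$inrm_nodes))
      if (nrow(x$inrm_edges)) {
        lines <- c(lines, "", "Edges above threshold:", md_table(x$inrm_edges))
      }
    }
  }
  if (!is.null(s$danp)) {
    lines <- c(lines, "", "## Influence weights (DANP)", md_table(s$danp$weights))
  }
  if (!is.null(s$topsis)) {
    lines <- c(lines, "", "## Performance evaluation (TOPSIS)")
    for (d in names(s$topsis$proximity)) {
      p <- s$topsis$proximity[[d]]
      tab <- data.frame(alternative = names(p), proximity = unname(p),
                        rank = match(names(p), s$topsis$ranking[[d]]))
      lines <- c(lines, sprintf("### %s", d), md_table(tab),
                 sprintf("Ranking: %s", paste(s$topsis$ranking[[d]], collapse = " > ")),
                 "")
    }
  }
  lines
}

# Drop bulky S3 internals (full topsis_result objects) from the JSON body.
strip_heavy <- function(stages) {
  if (!is.null(stages$topsis$proximity)) {
    stages$topsis$proximity <- lapply(stages$topsis$proximity, as.list)
  }
  if (!is.null(stages$topsis$results)) {
    stages$topsis$results <- lapply(stages$topsis$results, function(r) {
      list(proximity = as.list(r$proximity),
           separation_pos = as.list(r$separation_pos),
           separation_neg = as.list(r$separation_neg),
           positive_ideal = as.list(r$positive_ideal),
           negative_ideal = as.list(r$negative_ideal),
           ranking = r$ranking,
           degenerate = unname(any(r$degenerate_flags)))
    })
  }
  stages
}

md_table <- function(df, digits = 3) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = digits, format = "f"))
  header <- paste0("| ", paste(colnames(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, unname(rows))
}
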